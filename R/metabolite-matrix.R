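#' Metabolite abundance matrix with a processing stage
#'
#' A thin container around a samples-by-metabolites numeric matrix (NA =
#' missing) that records where the matrix sits in the transformation
#' pipeline. Stages advance only forward:
#' `raw -> filtered -> imputed -> residualized -> normalized`.
#'
#' @param abundance Numeric matrix, samples in rows (rownames = sample IDs),
#'   metabolites in columns (colnames = metabolite IDs).
#' @param stage One of `"raw"`, `"filtered"`, `"imputed"`, `"residualized"`,
#'   `"normalized"`.
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(abundance, stage = "raw") {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            !is.null(colnames(abundance)))
  stage <- match.arg(stage, metabolite_stages())
  structure(list(abundance = abundance, stage = stage),
            class = "metabolite_matrix")
}

metabolite_stages <- function() {
  c("raw", "filtered", "imputed", "residualized", "normalized")
}

advance_stage <- function(x, from, to) {
  stages <- metabolite_stages()
  if (x$stage != from) {
    stop(sprintf("expected matrix at stage '%s' but got '%s' (stages move only forward: %s)",
                 from, x$stage, paste(stages, collapse = " -> ")),
         call. = FALSE)
  }
  stopifnot(match(to, stages) > match(from, stages))
  x$stage <- to
  x
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  miss <- mean(is.na(x$abundance))
  cat(sprintf("<metabolite_matrix> %d samples x %d metabolites, stage '%s', %.1f%% missing\n",
              nrow(x$abundance), ncol(x$abundance), x$stage, 100 * miss))
  invisible(x)
}

#' @export
sample_ids.metabolite_matrix <- function(x) rownames(x$abundance)
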