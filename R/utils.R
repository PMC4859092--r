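#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist hclust median pt quantile rnorm runif sd var
#'   as.dendrogram kmeans p.adjust setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific 32-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

psf_log <- function(..., file = NULL) {
  msg <- paste0("[psfsom ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample-size bookkeeping of the lung-disease study design
#'
#' The per-class sample sizes of the lung compendium the method was designed
#' around (21 disease groups plus one healthy control), shipped as a
#' plain-text fixture for bookkeeping checks.
#'
#' @return Data frame with columns `class_group`, `lung_disease`,
#'   `abbreviation`, `n_samples`.
#' @export
lung_study_classes <- function() {
  utils::read.delim(system.file("extdata", "lung_disease_classes.tsv",
                                package = "psfsom", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
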