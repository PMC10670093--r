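# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so seeded generators do not
#' disturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' The three-compartment vocabulary, in canonical order.
#' @export
COMPARTMENTS <- c("ER", "mitochondria", "cytosol")

# Map free-text compartment labels to the canonical vocabulary; NA if unknown.
canon_compartment <- function(x) {
  key <- tolower(trimws(as.character(x)))
  lut <- c(
    "er" = "ER", "endoplasmic reticulum" = "ER",
    "mito" = "mitochondria", "mitochondria" = "mitochondria",
    "mitochondrion" = "mitochondria", "mitochondrial" = "mitochondria",
    "cyto" = "cytosol", "cytosol" = "cytosol", "cytosolic" = "cytosol",
    "cytoplasm" = "cytosol"
  )
  out <- unname(lut[key])
  out
}

# Deterministic TSV writer (no quoting surprises, "." decimal, no rownames).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
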