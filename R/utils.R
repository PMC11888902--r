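#' @keywords internal
#' @useDynLib bcgscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child-seed derivation: one user-facing seed fans out to the
# per-stage / per-recording seeds. Kept below 2^31 so it is a valid R seed.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 1299721) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bcg <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bcg(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0) stop_bcg(sprintf("`%s` must be positive", name))
  if (nonneg && x < 0) stop_bcg(sprintf("`%s` must be nonnegative", name))
  invisible(x)
}

BCG_CLASSES <- c("normotensive", "hypertensive")

# label encoding used throughout: hypertensive = 1 (positive class)
label_to_int <- function(label) {
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) stop_bcg("numeric labels must be 0/1")
    return(as.integer(label))
  }
  m <- match(label, BCG_CLASSES)
  if (anyNA(m)) stop_bcg("labels must be 'hypertensive' or 'normotensive'")
  as.integer(m - 1L)
}
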