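#' @useDynLib rivasm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test cov dist lm optimize pbeta pnorm qnorm
#'   rnorm runif sd setNames var rlnorm rgamma rmultinom p.adjust
#' @importFrom utils read.delim write.table combn head
NULL

#' Derive a reproducible child seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' run seed and a stable string label, so that enabling or disabling one
#' stage never perturbs another stage's random stream.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(label))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(paste(label, collapse = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
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
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Validate a square symmetric dissimilarity matrix
#'
#' @param d numeric matrix with matching row/column sample labels.
#' @param name label used in error messages.
#' @return `d`, with dimnames enforced, invisibly checked.
#' @export
as_sq_dist <- function(d, name = "d") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(name, " must be square")
  if (is.null(rownames(d)) && is.null(colnames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  } else if (is.null(rownames(d))) rownames(d) <- colnames(d)
  else if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (!isTRUE(all.equal(rownames(d), colnames(d)))) {
    stop(name, " row and column labels differ")
  }
  if (max(abs(d - t(d))) > 1e-12) stop(name, " is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop(name, " has a nonzero diagonal")
  diag(d) <- 0
  d
}

upper_vec <- function(d) d[upper.tri(d)]

check_shared_registry <- function(...) {
  mats <- list(...)
  ref <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(rownames(m), ref)) {
      stop("distance matrices do not share a sample registry")
    }
  }
  invisible(ref)
}
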