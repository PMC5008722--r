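# Set-partition machinery for the moments-to-cumulants expansion.
# kappa_n = sum over partitions P of {1..n} of
#           (-1)^(|P|-1) (|P|-1)! prod_{B in P} E[prod_{i in B} X_i].
# On mean-subtracted series every partition containing a singleton block
# vanishes, so only singleton-free partitions are evaluated
# (1, 1, 4, 11, 41, 162 partitions for orders 2..7).

set_partitions <- function(n) {
  key <- paste0("partitions_", n)
  if (!is.null(.sofisim_env[[key]])) return(.sofisim_env[[key]])
  build <- function(m) {
    if (m == 1L) return(list(list(1L)))
    prev <- build(m - 1L)
    out <- vector("list", 0L)
    for (p in prev) {
      for (b in seq_along(p)) {
        q <- p
        q[[b]] <- c(q[[b]], m)
        out[[length(out) + 1L]] <- q
      }
      out[[length(out) + 1L]] <- c(p, list(m))
    }
    out
  }
  res <- build(as.integer(n))
  .sofisim_env[[key]] <- res
  res
}

singleton_free_partitions <- function(n) {
  key <- paste0("sf_partitions_", n)
  if (!is.null(.sofisim_env[[key]])) return(.sofisim_env[[key]])
  res <- Filter(function(p) all(lengths(p) >= 2L), set_partitions(n))
  .sofisim_env[[key]] <- res
  res
}

partition_coefficient <- function(p) {
  np <- length(p)
  (-1)^(np - 1) * factorial(np - 1)
}

#' Joint cumulant of n time series
#'
#' Computes the n-variate joint cumulant at the given frame lags via the
#' moments-to-cumulants expansion over set partitions. Series are
#' mean-subtracted first (cumulants of order >= 2 are shift invariant), so
#' partitions containing singleton blocks drop out of the sum.
#'
#' Applied to n copies of the same series this is the n-th order
#' auto-cumulant; the order-2 case equals the (population-normalized) sample
#' covariance, i.e. cross-correlation of the centered series.
#'
#' @param traces list of n numeric vectors of equal length (n in 2..7). A
#'   matrix with n rows is also accepted.
#' @param lags integer frame lags: a scalar 0 (default, all zero lag) or a
#'   vector of n - 1 nonnegative lags applied to series 2..n (series 1 is at
#'   lag 0).
#' @return the scalar joint cumulant estimate.
#' @export
#' @examples
#' x <- rbinom(500, 1, 0.3)
#' joint_cumulant(list(x, x))          # variance of x (population form)
#' joint_cumulant(list(x, x, x))       # third cumulant
joint_cumulant <- function(traces, lags = 0L) {
  if (is.matrix(traces)) traces <- asplit(traces, 1)
  n <- length(traces)
  if (n < 2 || n > 7) stop("order must be between 2 and 7", call. = FALSE)
  len <- lengths(traces)
  if (length(unique(len)) != 1) stop("series must have equal length", call. = FALSE)
  T_ <- len[1]
  if (T_ <= n) stop("series too short for the requested order", call. = FALSE)
  member_lags <- expand_lags(lags, n)
  ml <- max(member_lags)
  if (T_ - ml < 2) stop("series too short for the requested lags", call. = FALSE)
  win <- seq_len(T_ - ml)
  xs <- lapply(seq_len(n), function(i) {
    xi <- as.numeric(traces[[i]])[win + member_lags[i]]
    xi - mean(xi)
  })
  acc <- 0
  for (p in singleton_free_partitions(n)) {
    term <- partition_coefficient(p)
    for (b in p) {
      prod_b <- xs[[b[1]]]
      for (i in b[-1]) prod_b <- prod_b * xs[[i]]
      term <- term * mean(prod_b)
    }
    acc <- acc + term
  }
  acc
}

expand_lags <- function(lags, n) {
  if (length(lags) == 1 && lags == 0) return(integer(n))
  if (length(lags) != n - 1)
    stop("lags must be a scalar zero or a vector of order - 1 lags", call. = FALSE)
  if (any(lags < 0)) stop("lags must be nonnegative", call. = FALSE)
  c(0L, as.integer(lags))
}
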