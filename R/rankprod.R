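# Math core: exact and approximate tail probabilities of the rank-product
# statistic RP = prod(r_i) for k ranks drawn i.i.d. uniform on {1..n}
# (the with-replacement null).

#' Count rank tuples with product below a bound
#'
#' Computes \eqn{T(k, n, x) = |\{(r_1,\dots,r_k) \in \{1..n\}^k :
#' \prod_i r_i \le x\}|}, the quantity underlying the exact left-tail
#' probability of the rank-product statistic under the with-replacement null.
#'
#' The count is evaluated by the memoized recursion
#' \eqn{T(k,n,x) = \sum_{r=1}^{\min(n,x)} T(k-1, n, \lfloor x/r \rfloor)}
#' with \eqn{T(0,n,x) = 1} for \eqn{x \ge 1}, implemented in C++ with
#' 128-bit integer arithmetic for the bound and its floor quotients.
#' Saturated subproblems (\eqn{x \ge n^k}) are closed off without recursion
#' and levels 1 and 2 use closed forms, so only the genuinely ambiguous
#' floor values are memoized.
#'
#' The returned value is an R double: it is an exact integer whenever the
#' count is below 2^53 (all small-instance regimes, including everything the
#' exhaustive-enumeration oracle can reach), and accurate to ~1e-18 relative
#' error beyond that.
#'
#' @param k Number of ranks (non-negative integer).
#' @param n Universe size (positive integer).
#' @param x Product bound: a non-negative numeric integer, or a decimal
#'   string for values above 2^53.  Must be below 2^127.
#' @param budget Maximum number of memoized states before the computation
#'   aborts with an error; guards against intractable instances.
#' @param ops_cap Cap on elementary loop iterations inside the counter, the
#'   runtime analogue of `budget` (state count alone does not bound the
#'   block-enumeration work).
#' @return The tuple count as a double.
#' @examples
#' count_tuples_leq(2, 3, 3)  # 5 tuples: (1,1),(1,2),(2,1),(1,3),(3,1)
#' count_tuples_leq(1, 5, 3)  # 3
#' @export
count_tuples_leq <- function(k, n, x, budget = 1e9, ops_cap = 2e9) {
  k <- check_count(k, "k", min = 0L)
  n <- check_count(n, "n", min = 1L)
  x_dec <- as_dec_string(x)
  res <- .rp_count_leq(k, n, x_dec, as.double(budget), as.double(ops_cap))
  if (!isTRUE(res$ok)) {
    if (identical(res$reason, "magnitude")) {
      stop("x = ", x_dec, " exceeds the 128-bit range of the exact counter",
           call. = FALSE)
    }
    stop("exact counting budget exceeded (", format(budget, scientific = TRUE),
         " memoized states)", call. = FALSE)
  }
  res$count
}

#' Exact rank-product tail probability
#'
#' Left-tail probability \eqn{P(RP \le \prod_i r_i)} of the rank product of
#' `length(ranks)` i.i.d. uniform ranks on `{1..n}`, computed by exact
#' lattice counting (see [count_tuples_leq()]).
#'
#' @param ranks Integer vector of observed ranks, each in `1..n`.
#' @param n Universe size.
#' @param budget Memoized-state budget for the exact counter.
#' @param ops_cap Iteration cap bounding the exact counter's runtime.
#' @return The exact p-value in `[n^-k, 1]`.
#' @examples
#' rankprod_pvalue_exact(c(1, 1), 3)  # 1/9
#' rankprod_pvalue_exact(100, 100)    # 1
#' @export
rankprod_pvalue_exact <- function(ranks, n, budget = 1e9, ops_cap = 2e9) {
  n <- check_count(n, "n", min = 1L)
  ranks <- check_ranks(ranks, n)
  prod_dec <- .rp_product_dec(ranks)
  if (!isTRUE(prod_dec$ok)) {
    stop("rank product exceeds the 128-bit range of the exact counter; ",
         "use the gamma approximation", call. = FALSE)
  }
  res <- .rp_count_leq(length(ranks), n, prod_dec$dec, as.double(budget),
                       as.double(ops_cap))
  if (!isTRUE(res$ok)) {
    stop("exact counting budget exceeded (", format(budget, scientific = TRUE),
         " memoized states)", call. = FALSE)
  }
  res$p
}

#' Gamma approximation to the rank-product tail probability
#'
#' Treats the scaled ranks \eqn{u_i = r_i/n} as i.i.d. continuous uniform on
#' (0,1], so that \eqn{s = \sum_i \ln(n/r_i)} is a sum of k unit-rate
#' exponentials and \eqn{P(RP \le \prod r_i) \approx Q(k, s)}, the upper
#' regularized incomplete gamma function (survival function of a
#' Gamma(shape = k, rate = 1) variable at s).
#'
#' For `k = 1` the approximation is exact: \eqn{Q(1, \ln(n/r)) = r/n}.
#'
#' @inheritParams rankprod_pvalue_exact
#' @param continuity If `TRUE`, use the midpoint correction
#'   \eqn{u_i = (r_i - 0.5)/n} instead of \eqn{r_i/n}.
#' @return Approximate p-value in (0, 1].
#' @examples
#' rankprod_pvalue_gamma(c(10, 10), 10)     # s = 0, p = 1
#' rankprod_pvalue_gamma(25, 100)           # = 25/100 (k = 1 is exact)
#' @export
rankprod_pvalue_gamma <- function(ranks, n, continuity = FALSE) {
  n <- check_count(n, "n", min = 1L)
  ranks <- check_ranks(ranks, n)
  u <- if (continuity) (ranks - 0.5) / n else ranks / n
  s <- -sum(log(u))
  pgamma(s, shape = length(ranks), rate = 1, lower.tail = FALSE)
}

#' Rank-product tail probability with method dispatch
#'
#' Computes the rank-product statistic of a set of ranks and its left-tail
#' p-value under the with-replacement null, choosing between the exact
#' counting recursion and the gamma approximation.
#'
#' With `method = "auto"` the exact method is used when the instance is
#' tractable: the product must fit in 128 bits and the projected memo size
#' (number of distinct floor values, about \eqn{2\sqrt{x}}, times k) must
#' stay under `budget`.  Otherwise the gamma approximation is used and
#' recorded in `method_used`.
#'
#' @inheritParams rankprod_pvalue_exact
#' @param method `"exact"`, `"gamma"`, or `"auto"`.
#' @param budget Memoized-state budget governing the auto dispatch (and
#'   capping a forced exact computation).
#' @param ops_cap Iteration cap bounding the exact counter's runtime; an
#'   auto dispatch that exceeds it falls back to the gamma approximation.
#' @param continuity Passed to [rankprod_pvalue_gamma()].
#' @return An object of class `"rank_product"`: a list with elements `k`,
#'   `n`, `rp` (the exact product as a decimal string), `rp_num` (the
#'   product as a double, `NA` when above 2^53), `log_stat`
#'   (\eqn{s = \sum \ln(n/r_i)}), `p_exact` (or `NA`), `p_gamma`, `p` (the
#'   dispatched value) and `method_used`.
#' @examples
#' rankprod_pvalue(c(1, 2), 10)$p          # 3/100
#' rankprod_pvalue(c(7, 3), 10, method = "gamma")$method_used
#' @export
rankprod_pvalue <- function(ranks, n, method = c("auto", "exact", "gamma"),
                            budget = 1e7, ops_cap = 1e7, continuity = FALSE) {
  method <- match.arg(method)
  n <- check_count(n, "n", min = 1L)
  ranks <- check_ranks(ranks, n)
  k <- length(ranks)

  prod_dec <- .rp_product_dec(ranks)
  log_rp <- sum(log(ranks))
  rp_string <- prod_dec$dec
  rp_num <- if (log_rp < 53 * log(2)) prod(as.double(ranks)) else NA_real_

  p_gamma <- rankprod_pvalue_gamma(ranks, n, continuity = continuity)

  use_exact <- switch(method,
    exact = TRUE,
    gamma = FALSE,
    auto = isTRUE(prod_dec$ok) && exact_state_estimate(k, log_rp) <= budget
  )

  p_exact <- NA_real_
  method_used <- "gamma"
  if (use_exact) {
    if (!isTRUE(prod_dec$ok)) {
      stop("rank product exceeds the 128-bit range of the exact counter; ",
           "use method = \"gamma\" or \"auto\"", call. = FALSE)
    }
    res <- .rp_count_leq(k, n, prod_dec$dec, as.double(budget),
                         as.double(ops_cap))
    if (isTRUE(res$ok)) {
      p_exact <- res$p
      method_used <- "exact"
    } else if (method == "exact") {
      stop("exact counting budget exceeded (",
           format(budget, scientific = TRUE), " memoized states)",
           call. = FALSE)
    }
  }

  structure(
    list(
      k = k, n = n,
      rp = rp_string, rp_num = rp_num,
      log_stat = k * log(n) - log_rp,
      p_exact = p_exact,
      p_gamma = p_gamma,
      p = if (method_used == "exact") p_exact else p_gamma,
      method_used = method_used
    ),
    class = "rank_product"
  )
}

#' @export
print.rank_product <- function(x, ...) {
  cat("Rank product statistic\n")
  cat("  k =", x$k, " n =", x$n, "\n")
  cat("  RP =", x$rp, "\n")
  cat("  log-statistic s =", format(x$log_stat, digits = 6), "\n")
  if (!is.na(x$p_exact)) {
    cat("  p (exact) =", format(x$p_exact, digits = 6), "\n")
  }
  cat("  p (gamma) =", format(x$p_gamma, digits = 6), "\n")
  cat("  method used:", x$method_used, "\n")
  invisible(x)
}

# Projected memo size of the exact DP: about 2*sqrt(x) distinct floor
# values per level, k levels.  Computed in log space so huge products never
# overflow.  This is the auto-dispatch rule; the C++ counter additionally
# enforces the budget on the states actually materialized.
exact_state_estimate <- function(k, log_rp) {
  log_states <- 0.5 * log_rp + log(2 * max(k, 1))
  if (log_states > log(.Machine$double.xmax)) Inf else exp(log_states)
}

# -- small helpers -----------------------------------------------------------

check_count <- function(v, what, min) {
  if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != floor(v) || v < min) {
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(v)
}

check_ranks <- function(ranks, n) {
  if (length(ranks) < 1L) stop("at least one rank is required", call. = FALSE)
  if (!is.numeric(ranks) || anyNA(ranks) || any(ranks != floor(ranks))) {
    stop("ranks must be integers", call. = FALSE)
  }
  if (any(ranks < 1L) || any(ranks > n)) {
    stop("ranks must lie in 1..n (n = ", n, ")", call. = FALSE)
  }
  as.integer(ranks)
}

as_dec_string <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[0-9]+$", x)) {
      stop("x must be a non-negative integer or decimal string", call. = FALSE)
    }
    return(x)
  }
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x != floor(x)) {
    stop("x must be a non-negative integer or decimal string", call. = FALSE)
  }
  if (x > 2^53) {
    stop("numeric x above 2^53 is not exactly representable; ",
         "pass x as a decimal string", call. = FALSE)
  }
  sprintf("%.0f", x)
}
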