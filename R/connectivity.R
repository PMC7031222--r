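# Scoring one signature against one ranked drug profile, in both
# directions, and aggregating treatment instances per compound.
#
# Rank convention (used everywhere): rank 1 = the gene most up-regulated by
# the treatment; the reflected rank r~ = n + 1 - r maps "near the top" to
# "near the bottom" and represents down-regulation.

#' Rank a profile of treatment scores
#'
#' Converts per-gene scores into ranks with 1 = largest score (most
#' up-regulated).  Ties are broken deterministically by gene id, ascending.
#'
#' @param scores Named numeric vector (names are gene ids); all finite.
#' @return Named integer vector of ranks forming a permutation of
#'   `1..length(scores)`.
#' @export
rank_profile <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (is.null(names(scores)) || !all(nzchar(names(scores)))) {
    stop("scores must be named by gene id", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  ord <- order(-scores, names(scores))
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  names(ranks) <- names(scores)
  ranks
}

# rank matrix for a profile_matrix: returns genes x instances integer matrix
# of ranks (identity if the matrix already holds ranks)
rank_matrix <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (pm$is_ranks) {
    mat <- pm$values
    storage.mode(mat) <- "integer"
    return(mat)
  }
  apply(pm$values, 2, function(col) {
    rank_profile(stats::setNames(col, pm$genes))
  })
}

#' Connectivity score of a signature against one ranked profile
#'
#' Pools the signature into a single rank-product statistic: for the
#' positive match the ranks of the up-genes and the reflected ranks
#' `n + 1 - r` of the down-genes (a profile mimicking the signature drives
#' both towards 1); the negative match swaps the roles.  An empty direction
#' set simply contributes no ranks.
#'
#' @param sig A [signature()] already restricted to the profile's universe.
#' @param ranks Named integer vector of profile ranks (permutation of
#'   `1..n`), e.g. one column of [rank_matrix] or [rank_profile()].
#' @param method,budget,ops_cap Passed to [rankprod_pvalue()].
#' @return A one-row data frame: `signature_name`, `k_up`, `k_down`,
#'   `p_pos`, `p_neg`, `method_used`.
#' @export
connectivity_score <- function(sig, ranks, method = c("auto", "exact", "gamma"),
                               budget = 1e7, ops_cap = 1e7) {
  method <- match.arg(method)
  stopifnot(inherits(sig, "signature"))
  n <- length(ranks)
  missing <- setdiff(c(sig$up, sig$down), names(ranks))
  if (length(missing)) {
    stop("signature '", sig$name, "' has genes outside the profile ",
         "universe (restrict first): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  r_up <- unname(ranks[sig$up])
  r_down <- unname(ranks[sig$down])
  pooled_pos <- c(r_up, n + 1L - r_down)
  pooled_neg <- c(n + 1L - r_up, r_down)
  if (!length(pooled_pos)) stop("empty signature", call. = FALSE)
  rp_pos <- rankprod_pvalue(pooled_pos, n, method, budget, ops_cap)
  rp_neg <- rankprod_pvalue(pooled_neg, n, method, budget, ops_cap)
  data.frame(
    signature_name = sig$name,
    k_up = length(r_up), k_down = length(r_down),
    p_pos = rp_pos$p, p_neg = rp_neg$p,
    method_used = paste(unique(c(rp_pos$method_used, rp_neg$method_used)),
                        collapse = "+"),
    stringsAsFactors = FALSE
  )
}

#' Score a signature panel against every instance of a profile matrix
#'
#' Restricts each signature to the matrix universe, ranks every instance
#' column (unless the matrix already holds ranks), and computes the
#' positive and negative connectivity score for every (signature, instance)
#' pair.
#'
#' @param panel A [signature_panel()].
#' @param pm A `profile_matrix` with instance annotations.
#' @inheritParams connectivity_score
#' @return A long-form data frame with one row per (signature, instance):
#'   `signature_name`, `instance_id`, `compound_id`, `cell_line`, `k_up`,
#'   `k_down`, `p_pos`, `p_neg`, `method_used`.
#' @export
score_panel <- function(panel, pm, method = c("auto", "exact", "gamma"),
                        budget = 1e7, ops_cap = 1e7) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "signature_panel"), inherits(pm, "profile_matrix"))
  if (is.null(pm$annotations)) {
    stop("profile matrix has no instance annotations", call. = FALSE)
  }
  rmat <- rank_matrix(pm)
  n <- nrow(rmat)
  n_inst <- length(pm$instances)
  blocks <- lapply(panel, function(sig) {
    sig_r <- restrict_to_universe(sig, pm$genes)
    up_idx <- match(sig_r$up, pm$genes)
    down_idx <- match(sig_r$down, pm$genes)
    k <- length(up_idx) + length(down_idx)

    score_dir <- function(reflect_up) {
      # pooled rank matrix, k x instances
      pooled <- rbind(
        if (reflect_up) n + 1L - rmat[up_idx, , drop = FALSE]
        else rmat[up_idx, , drop = FALSE],
        if (reflect_up) rmat[down_idx, , drop = FALSE]
        else n + 1L - rmat[down_idx, , drop = FALSE]
      )
      log_rp <- colSums(log(pooled))
      # columns the auto dispatch would certify exactly get the full
      # per-instance treatment; the rest take the vectorized gamma tail
      exact_cols <- if (method == "gamma") rep(FALSE, n_inst) else {
        est <- vapply(log_rp, function(lr) exact_state_estimate(k, lr),
                      numeric(1))
        fits <- log_rp < 127 * log(2)
        if (method == "exact" && !all(fits)) {
          stop("rank product exceeds the 128-bit range of the exact ",
               "counter; use method = \"gamma\" or \"auto\"", call. = FALSE)
        }
        if (method == "exact") fits else fits & est <= budget
      }
      # same arithmetic as rankprod_pvalue_gamma, so the two routes agree
      # bitwise
      p <- pgamma(-colSums(log(pooled / n)), shape = k, rate = 1,
                  lower.tail = FALSE)
      used <- rep("gamma", n_inst)
      for (j in which(exact_cols)) {
        rp <- rankprod_pvalue(pooled[, j], n, method, budget, ops_cap)
        p[j] <- rp$p
        used[j] <- rp$method_used
      }
      list(p = p, used = used)
    }

    pos <- score_dir(reflect_up = FALSE)
    neg <- score_dir(reflect_up = TRUE)
    data.frame(
      signature_name = sig_r$name,
      instance_id = pm$instances,
      compound_id = pm$annotations$compound_id,
      cell_line = pm$annotations$cell_line,
      k_up = length(up_idx), k_down = length(down_idx),
      p_pos = pos$p, p_neg = neg$p,
      method_used = ifelse(pos$used == neg$used, pos$used,
                           paste(pos$used, neg$used, sep = "+")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Combine p-values by Fisher's method
#'
#' \eqn{X = -2 \sum_i \ln p_i} follows a chi-squared distribution with
#' `2 * length(p)` degrees of freedom when the `p_i` are independent and
#' uniform; the combined p-value is its upper tail at X.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p) {
  if (!length(p)) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  x <- -2 * sum(log(p))
  pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Aggregate instance-level connectivity scores per compound
#'
#' Treatment instances of the same compound (different cell lines, doses,
#' replicates) are combined with Fisher's method, separately for the
#' positive and negative direction, within each signature.  With
#' `stratify_cell_line = TRUE` instances are first combined within each
#' cell line and the per-cell-line p-values are then combined.
#'
#' @param results Long-form data frame from [score_panel()] (or rows of
#'   [connectivity_score()] plus `compound_id`/`cell_line` columns).
#' @param stratify_cell_line Combine within cell lines first.
#' @return Data frame with one row per (compound, signature):
#'   `compound_id`, `signature_name`, `m_instances`, `p_pos`, `p_neg`.
#' @export
aggregate_instances <- function(results, stratify_cell_line = FALSE) {
  if (!nrow(results)) stop("no connectivity results to aggregate", call. = FALSE)
  need <- c("compound_id", "signature_name", "p_pos", "p_neg")
  stopifnot(all(need %in% names(results)))
  if (any(is.na(results$p_pos) | results$p_pos <= 0 | results$p_pos > 1,
          is.na(results$p_neg) | results$p_neg <= 0 | results$p_neg > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (stratify_cell_line) {
    # combine within cell line first, then across cell lines
    within <- aggregate_by_key(results,
                               paste(results$compound_id,
                                     results$signature_name,
                                     results$cell_line, sep = "\r"))
    within$compound_id <- sub("\r.*", "", within$key)
    within$signature_name <- vapply(strsplit(within$key, "\r", fixed = TRUE),
                                    `[[`, character(1), 2)
    out <- aggregate_by_key(within, paste(within$compound_id,
                                          within$signature_name, sep = "\r"),
                            m_col = within$m_instances)
  } else {
    out <- aggregate_by_key(results, paste(results$compound_id,
                                           results$signature_name,
                                           sep = "\r"))
  }
  out$compound_id <- sub("\r.*", "", out$key)
  out$signature_name <- sub(".*\r", "", out$key)
  out <- out[order(out$compound_id, out$signature_name),
             c("compound_id", "signature_name", "m_instances",
               "p_pos", "p_neg"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fisher-combine p_pos/p_neg within groups of `key` (vectorized);
# m_col overrides the per-row instance count (used by stratification)
aggregate_by_key <- function(df, key, m_col = NULL) {
  key <- factor(key)
  counts <- as.vector(table(key))
  m <- if (is.null(m_col)) counts else as.vector(rowsum(m_col, key))
  combine <- function(p) {
    x <- -2 * as.vector(rowsum(log(p), key))
    pchisq(x, df = 2 * counts, lower.tail = FALSE)
  }
  data.frame(
    key = levels(key),
    m_instances = as.integer(m),
    p_pos = combine(df$p_pos),
    p_neg = combine(df$p_neg),
    stringsAsFactors = FALSE
  )
}
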