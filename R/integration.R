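# Cross-signature integration: per-signature compound rankings are
# combined with a meta-level rank product (the same exact machinery used at
# the gene level, with the number of compounds as the universe size),
# yielding one statistically ranked list per direction, with BH FDR.

#' Integrate per-signature compound scores across the panel
#'
#' For each signature, compounds are ranked by the direction's combined
#' p-value, ascending (ties broken by compound id, ascending), giving ranks
#' \eqn{\rho_s \in 1..m}.  The meta rank product \eqn{\prod_s \rho_s} is
#' referred to its exact with-replacement null over `m` compounds and `S`
#' signatures, the list is sorted by integrated p-value and BH-adjusted.
#'
#' @param scores Data frame from [aggregate_instances()]: one row per
#'   (compound, signature) with `p_pos` and `p_neg`.  Every compound must
#'   have a score for every signature.
#' @param direction `"positive"` or `"negative"`.
#' @param budget,ops_cap Passed to the meta-level [rankprod_pvalue()].
#' @return A data frame with one row per compound: `compound_id`,
#'   `direction`, per-signature combined p's (`p__<signature>`),
#'   per-signature ranks (`rho__<signature>`), `meta_rp` (decimal string),
#'   `p_integrated`, `q_fdr`, `final_rank`; sorted by `p_integrated`.
#' @export
integrate_signatures <- function(scores, direction = c("positive", "negative"),
                                 budget = 1e7, ops_cap = 1e7) {
  direction <- match.arg(direction)
  need <- c("compound_id", "signature_name", "p_pos", "p_neg")
  stopifnot(all(need %in% names(scores)))
  p_col <- if (direction == "positive") "p_pos" else "p_neg"

  sigs <- sort(unique(scores$signature_name))
  compounds <- sort(unique(scores$compound_id))
  m <- length(compounds)
  s_count <- length(sigs)

  # completeness check: every compound needs every signature
  have <- table(factor(scores$compound_id, compounds),
                factor(scores$signature_name, sigs))
  if (any(have != 1L)) {
    bad <- which(have != 1L, arr.ind = TRUE)[1, ]
    stop("incomplete panel: compound '", compounds[bad[[1]]],
         "' lacks a score for signature '", sigs[bad[[2]]], "'",
         call. = FALSE)
  }

  p_mat <- matrix(NA_real_, m, s_count, dimnames = list(compounds, sigs))
  idx <- cbind(match(scores$compound_id, compounds),
               match(scores$signature_name, sigs))
  p_mat[idx] <- scores[[p_col]]

  # per-signature compound ranks, ties broken by compound id (rows are
  # already in compound id order)
  rho <- apply(p_mat, 2, function(p) {
    rr <- integer(m)
    rr[order(p, compounds)] <- seq_len(m)
    rr
  })
  if (m == 1L) rho <- matrix(rho, 1L, s_count)

  meta <- lapply(seq_len(m), function(i) {
    rankprod_pvalue(rho[i, ], m, method = "auto", budget = budget,
                    ops_cap = ops_cap)
  })
  p_int <- vapply(meta, `[[`, numeric(1), "p")

  out <- data.frame(
    compound_id = compounds,
    direction = direction,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(s_count)) out[[paste0("p__", sigs[[j]])]] <- p_mat[, j]
  for (j in seq_len(s_count)) out[[paste0("rho__", sigs[[j]])]] <- rho[, j]
  out$meta_rp <- vapply(meta, `[[`, character(1), "rp")
  out$p_integrated <- p_int
  out$q_fdr <- bh_fdr(p_int)
  out <- out[order(out$p_integrated, out$compound_id), , drop = FALSE]
  out$final_rank <- seq_len(m)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up q-values with running-minimum enforcement; input order is
#' preserved in the output.  (Thin validated wrapper over
#' [stats::p.adjust()] with `method = "BH"`.)
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals) | pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Run the full repositioning pipeline
#'
#' Executes translate (optional) -> restrict -> rank -> connectivity
#' scoring per (signature, instance) -> per-compound instance aggregation
#' -> cross-signature integration per direction -> BH FDR, and writes
#' `positive.tsv`, `negative.tsv` and `report.txt` to the output
#' directory.  Fully deterministic given its inputs.
#'
#' @param panel A [signature_panel()] (source gene space).
#' @param pm A `profile_matrix` with instance annotations.
#' @param ortholog_map Optional [ortholog_map()]; required when
#'   `translate = TRUE`.
#' @param translate Translate the panel through the ortholog map first.
#' @param ortholog_policy Passed to [translate_signature()].
#' @param method,budget,ops_cap Rank-product method controls.
#' @param stratify_cell_line Passed to [aggregate_instances()].
#' @param output_dir Output directory, created if needed; `NULL` writes
#'   nothing.
#' @return A list with `positive`, `negative` (integrated tables),
#'   `scores` (instance-level), `compound_scores` (aggregated) and
#'   `report` (character vector).
#' @export
run_repositioning <- function(panel, pm, ortholog_map = NULL,
                              translate = !is.null(ortholog_map),
                              ortholog_policy = "expand",
                              method = "auto", budget = 1e7, ops_cap = 1e7,
                              stratify_cell_line = FALSE,
                              output_dir = NULL) {
  stopifnot(inherits(panel, "signature_panel"), inherits(pm, "profile_matrix"))
  if (translate) {
    if (is.null(ortholog_map)) {
      stop("translation requested but no ortholog map supplied", call. = FALSE)
    }
    panel <- signature_panel(lapply(panel, translate_signature,
                                    map = ortholog_map,
                                    policy = ortholog_policy))
  }
  restricted <- signature_panel(lapply(panel, restrict_to_universe,
                                       universe = pm$genes))
  scores <- score_panel(restricted, pm, method = method, budget = budget,
                        ops_cap = ops_cap)
  compound_scores <- aggregate_instances(scores,
                                         stratify_cell_line = stratify_cell_line)
  positive <- integrate_signatures(compound_scores, "positive",
                                   budget = budget, ops_cap = ops_cap)
  negative <- integrate_signatures(compound_scores, "negative",
                                   budget = budget, ops_cap = ops_cap)

  m <- length(unique(compound_scores$compound_id))
  report <- c(
    paste0("rpconnect ", as.character(packageVersion("rpconnect"))),
    paste0("gene universe n = ", length(pm$genes)),
    paste0("instances = ", length(pm$instances), ", compounds m = ", m),
    paste0("signatures S = ", length(restricted)),
    vapply(restricted, function(s) {
      paste0("  ", s$name, ": k_up = ", length(s$up),
             ", k_down = ", length(s$down))
    }, character(1)),
    paste0("method tallies: ",
           paste(names(table(scores$method_used)), table(scores$method_used),
                 sep = "=", collapse = ", "))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(positive, file.path(output_dir, "positive.tsv"))
    write_results(negative, file.path(output_dir, "negative.tsv"))
    writeLines(report, file.path(output_dir, "report.txt"))
  }
  list(positive = positive, negative = negative, scores = scores,
       compound_scores = compound_scores, report = report)
}
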