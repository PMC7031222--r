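# Up/down signatures: extraction from differential-expression tables,
# cross-species translation through an ortholog map, and restriction to a
# profile-matrix gene universe.
#
# A signature is a pair of disjoint gene sets (up-regulated, down-regulated)
# summarizing one time-point contrast; a panel is an ordered, uniquely-named
# collection of signatures that together represent the stages of the
# biological process being matched.

#' Construct a signature
#'
#' @param name Signature name (unique within a panel).
#' @param up,down Character vectors of gene ids; must be disjoint and not
#'   both empty.  Stored sorted and deduplicated.
#' @param contrast_label Label of the originating contrast.
#' @return An object of class `signature`.
#' @export
signature <- function(name, up, down, contrast_label = name) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (length(intersect(up, down))) {
    stop("up and down gene sets overlap: ",
         paste(utils::head(intersect(up, down), 3), collapse = ", "),
         call. = FALSE)
  }
  if (!length(up) && !length(down)) {
    stop("signature '", name, "' is empty", call. = FALSE)
  }
  structure(
    list(name = name, up = up, down = down, contrast_label = contrast_label),
    class = "signature"
  )
}

#' @export
print.signature <- function(x, ...) {
  cat("Signature '", x$name, "' (contrast ", x$contrast_label, "): ",
      length(x$up), " up, ", length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Construct a signature panel
#'
#' @param signatures A list of [signature()] objects with unique names.
#' @return A named list of class `signature_panel`.
#' @export
signature_panel <- function(signatures) {
  stopifnot(length(signatures) >= 1L)
  if (!all(vapply(signatures, inherits, logical(1), "signature"))) {
    stop("all panel members must be signature objects", call. = FALSE)
  }
  nms <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("signature names must be unique (duplicated: ",
         nms[duplicated(nms)][[1]], ")", call. = FALSE)
  }
  structure(stats::setNames(signatures, nms), class = "signature_panel")
}

#' @export
print.signature_panel <- function(x, ...) {
  cat("Signature panel with", length(x), "signatures\n")
  for (s in x) {
    cat("  ", s$name, ": ", length(s$up), " up / ", length(s$down),
        " down\n", sep = "")
  }
  invisible(x)
}

#' Extract an up/down signature from a differential-expression table
#'
#' Thresholding replaces the manual curation step of signature selection:
#' up-genes satisfy `log2fc >= lfc_min` and `p_adj <= q_max`, down-genes
#' `log2fc <= -lfc_min` and `p_adj <= q_max`.  If more than `max_size`
#' genes qualify, the `max_size` genes with largest `|log2fc|` are kept
#' (ties broken by gene id, ascending).
#'
#' @param de A [de_table()].
#' @param lfc_min Minimum absolute log2 fold change (> 0).
#' @param q_max Maximum adjusted p-value, in (0, 1].
#' @param min_size Minimum total signature size; fewer qualifying genes is
#'   an error.
#' @param max_size Maximum total signature size.
#' @param name Signature name; defaults to the contrast label.
#' @return A [signature()].
#' @export
extract_signature <- function(de, lfc_min = 1, q_max = 0.05,
                              min_size = 10, max_size = 500, name = NULL) {
  stopifnot(inherits(de, "de_table"), lfc_min > 0, q_max > 0, q_max <= 1,
            min_size >= 1, max_size >= min_size)
  contrast <- attr(de, "contrast_label")
  if (is.null(name)) name <- contrast
  sel <- de$p_adj <= q_max & abs(de$log2fc) >= lfc_min
  hits <- de[sel, , drop = FALSE]
  if (nrow(hits) < min_size) {
    stop("signature too small for contrast '", contrast, "': ", nrow(hits),
         " genes pass (lfc_min = ", lfc_min, ", q_max = ", q_max,
         "), need ", min_size, call. = FALSE)
  }
  if (nrow(hits) > max_size) {
    ord <- order(-abs(hits$log2fc), hits$gene_id)
    hits <- hits[ord[seq_len(max_size)], , drop = FALSE]
  }
  signature(
    name = name,
    up = hits$gene_id[hits$log2fc > 0],
    down = hits$gene_id[hits$log2fc < 0],
    contrast_label = contrast
  )
}

#' Translate a signature across species through an ortholog map
#'
#' Each source gene is replaced by target genes according to `policy`:
#' `"expand"` keeps all targets, `"drop_ambiguous"` keeps only genes with
#' exactly one target, `"first"` keeps the lexicographically smallest
#' target.  Unmapped genes are dropped.  A target reached from both the up
#' and the down set is directionally ambiguous and is removed from both;
#' such conflicts are reported in the `conflicts` attribute.
#'
#' @param sig A [signature()] in source gene space.
#' @param map An [ortholog_map()].
#' @param policy One-to-many resolution policy.
#' @return The translated [signature()], with attribute `conflicts`.
#' @export
translate_signature <- function(sig, map,
                                policy = c("expand", "drop_ambiguous", "first")) {
  policy <- match.arg(policy)
  stopifnot(inherits(sig, "signature"))
  translate_set <- function(genes) {
    hits <- map[map$source_gene %in% genes, , drop = FALSE]
    if (!nrow(hits)) return(character(0))
    targets <- split(hits$target_gene, hits$source_gene)
    mapped <- switch(policy,
      expand = unlist(targets, use.names = FALSE),
      drop_ambiguous = unlist(targets[lengths(targets) == 1L],
                              use.names = FALSE),
      first = vapply(targets, function(t) sort(t)[[1]], character(1))
    )
    unique(mapped)
  }
  up <- translate_set(sig$up)
  down <- translate_set(sig$down)
  conflicts <- intersect(up, down)
  up <- setdiff(up, conflicts)
  down <- setdiff(down, conflicts)
  if (!length(up) && !length(down)) {
    stop("untranslatable signature '", sig$name,
         "': no genes left after mapping", call. = FALSE)
  }
  out <- signature(sig$name, up, down, sig$contrast_label)
  attr(out, "conflicts") <- sort(conflicts)
  out
}

#' Restrict a signature to a gene universe
#'
#' Signature genes absent from the profile matrix cannot be ranked, so both
#' sets are intersected with the universe before scoring.
#'
#' @param sig A [signature()].
#' @param universe Character vector of genes (the profile matrix rows).
#' @return The restricted [signature()] with attributes `k_up` and `k_down`
#'   (retained counts).
#' @export
restrict_to_universe <- function(sig, universe) {
  stopifnot(inherits(sig, "signature"))
  up <- intersect(sig$up, universe)
  down <- intersect(sig$down, universe)
  if (!length(up) && !length(down)) {
    stop("signature '", sig$name, "' is disjoint from the profile universe",
         call. = FALSE)
  }
  out <- signature(sig$name, up, down, sig$contrast_label)
  attr(out, "k_up") <- length(up)
  attr(out, "k_down") <- length(down)
  out
}

#' Convert a signature panel to GMT sets and back
#'
#' Each signature becomes two GMT lines, `<name>_UP` and `<name>_DN`,
#' carrying the contrast label as the description.
#'
#' @param panel A [signature_panel()].
#' @return A list suitable for [write_gmt()].
#' @export
panel_to_gmt <- function(panel) {
  stopifnot(inherits(panel, "signature_panel"))
  out <- list()
  for (s in panel) {
    out[[paste0(s$name, "_UP")]] <-
      list(name = paste0(s$name, "_UP"), description = s$contrast_label,
           genes = s$up)
    out[[paste0(s$name, "_DN")]] <-
      list(name = paste0(s$name, "_DN"), description = s$contrast_label,
           genes = s$down)
  }
  out
}

#' @rdname panel_to_gmt
#' @param sets A list of GMT sets with paired `_UP`/`_DN` names.
#' @return `gmt_to_panel()`: a [signature_panel()].
#' @export
gmt_to_panel <- function(sets) {
  nms <- vapply(sets, `[[`, character(1), "name")
  base <- unique(sub("_(UP|DN)$", "", nms))
  sigs <- lapply(base, function(b) {
    i_up <- match(paste0(b, "_UP"), nms)
    i_dn <- match(paste0(b, "_DN"), nms)
    up_set <- if (is.na(i_up)) NULL else sets[[i_up]]
    dn_set <- if (is.na(i_dn)) NULL else sets[[i_dn]]
    desc <- c(up_set$description, dn_set$description, b)[[1]]
    signature(b,
              up = if (is.null(up_set)) character(0) else up_set$genes,
              down = if (is.null(dn_set)) character(0) else dn_set$genes,
              contrast_label = desc)
  })
  signature_panel(sigs)
}
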