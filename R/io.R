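# Readers and writers for the external formats the pipeline touches:
# GMT gene sets, GCT 1.2 / TSV profile matrices, instance annotations,
# two-column ortholog maps, three-column differential-expression tables,
# and the integrated results table.
#
# Dialect rules (fixed by design): tab-separated, UTF-8, mandatory header
# row for DE / ortholog / annotation tables; gene identifiers are matched
# exactly and case-sensitively throughout.

fmt_stop <- function(path, ...) {
  stop("format error in '", path, "': ", ..., call. = FALSE)
}

#' Read a GMT gene-set file
#'
#' Each line holds a set name, a description, and the member genes, all
#' tab-separated.  Duplicate genes within a line are removed keeping the
#' first occurrence; gene order is otherwise preserved.
#'
#' @param path Path to a GMT file.
#' @return A named list; each element is a list with `name`, `description`
#'   and `genes` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; count separators directly
    n_fields <- nchar(lines[[i]]) -
      nchar(gsub("\t", "", lines[[i]], fixed = TRUE)) + 1L
    if (n_fields < 3L) {
      fmt_stop(path, "line ", i, " has fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    genes <- genes[!is.na(genes)]
    genes <- genes[nzchar(genes)]
    out[[i]] <- list(
      name = fields[[1]],
      description = fields[[2]],
      genes = genes[!duplicated(genes)]
    )
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A list as returned by [read_gmt()], or a list of lists with
#'   `name`, `description` and `genes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    name <- s$name
    desc <- if (is.null(s$description)) "na" else s$description
    if (!nzchar(name)) stop("GMT set names must be non-empty", call. = FALSE)
    if (grepl("\t", name, fixed = TRUE) || grepl("\t", desc, fixed = TRUE)) {
      stop("GMT set names and descriptions must not contain tabs",
           call. = FALSE)
    }
    # an empty set still gets a third (empty) field so the line stays valid
    genes <- if (length(s$genes)) s$genes else ""
    paste(c(name, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-perturbation profile matrix
#'
#' Reads a genes x instances matrix of treatment scores or precomputed
#' ranks, in GCT 1.2 (`#1.2` header, dims line, Name/Description columns)
#' or plain TSV (header of instance ids, first column gene ids).
#'
#' Value type is auto-detected: the matrix is treated as ranks if and only
#' if every column is a permutation of `1..n`.  A scores matrix whose
#' columns happen to be permutations would therefore be misread as ranks;
#' pass `values = "scores"` to override.
#'
#' @param path Path to the matrix file.
#' @param dialect `"auto"` (by extension), `"gct"` or `"tsv"`.
#' @param values `"auto"`, `"ranks"` or `"scores"`.
#' @param annotations Optional path to the instance annotation table (TSV
#'   with header `instance_id`, `compound_id`, `cell_line`), attached to
#'   the result.
#' @return A `profile_matrix` object: list with `genes`, `instances`,
#'   `values` (numeric matrix), `is_ranks` and `annotations`.
#' @export
read_profile_matrix <- function(path, dialect = c("auto", "gct", "tsv"),
                                values = c("auto", "ranks", "scores"),
                                annotations = NULL) {
  dialect <- match.arg(dialect)
  values <- match.arg(values)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "gct") "gct" else "tsv"
  }
  if (dialect == "gct") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 3L || trimws(lines[[1]]) != "#1.2") {
      fmt_stop(path, "not a GCT 1.2 file (missing '#1.2' header)")
    }
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[[2]]), "[ \t]+")[[1]]))
    if (length(dims) != 2L || anyNA(dims)) {
      fmt_stop(path, "malformed dims line")
    }
    body <- read.delim(text = lines[-(1:2)], check.names = FALSE,
                       stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(body) != dims[[1]] || ncol(body) - 2L != dims[[2]]) {
      fmt_stop(path, "dims line says ", dims[[1]], " x ", dims[[2]],
               " but body is ", nrow(body), " x ", ncol(body) - 2L)
    }
    genes <- body[[1]]
    mat_chr <- as.matrix(body[-(1:2)])
  } else {
    body <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                       colClasses = "character")
    if (ncol(body) < 2L) fmt_stop(path, "expected gene column plus instances")
    genes <- body[[1]]
    mat_chr <- as.matrix(body[-1])
  }
  if (anyDuplicated(genes)) {
    fmt_stop(path, "duplicated gene ids (first: ",
             genes[duplicated(genes)][[1]], ")")
  }
  mat <- suppressWarnings(array(as.numeric(mat_chr), dim = dim(mat_chr)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    fmt_stop(path, "non-numeric value at row ", bad[[1]], ", instance column ",
             bad[[2]], " ('", mat_chr[bad[[1]], bad[[2]]], "')")
  }
  dimnames(mat) <- list(genes, colnames(mat_chr))
  ann <- if (!is.null(annotations)) read_instance_annotations(annotations)
  profile_matrix(mat, values = values, annotations = ann)
}

#' Construct a profile matrix from a numeric matrix
#'
#' @param mat Numeric genes x instances matrix with row and column names.
#' @param values `"auto"`, `"ranks"` or `"scores"`; with `"auto"`, columns
#'   that all form permutations of `1..n` are treated as ranks.
#' @param annotations Optional data frame with columns `instance_id`,
#'   `compound_id`, `cell_line`, one row per instance.
#' @return A `profile_matrix` object.
#' @export
profile_matrix <- function(mat, values = c("auto", "ranks", "scores"),
                           annotations = NULL) {
  values <- match.arg(values)
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("profile matrix needs gene rownames and instance colnames",
         call. = FALSE)
  }
  is_ranks <- switch(values,
    ranks = TRUE,
    scores = FALSE,
    auto = all_columns_permutations(mat)
  )
  if (values == "ranks" && !all_columns_permutations(mat)) {
    stop("values = \"ranks\" but some column is not a permutation of 1..n",
         call. = FALSE)
  }
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations, colnames(mat))
  }
  structure(
    list(genes = rownames(mat), instances = colnames(mat), values = mat,
         is_ranks = is_ranks, annotations = annotations),
    class = "profile_matrix"
  )
}

all_columns_permutations <- function(mat) {
  n <- nrow(mat)
  all(apply(mat, 2, function(col) {
    !anyNA(col) && all(col == floor(col)) && all(col >= 1) && all(col <= n) &&
      !anyDuplicated(col)
  }))
}

validate_annotations <- function(ann, instances) {
  need <- c("instance_id", "compound_id", "cell_line")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (anyDuplicated(ann$instance_id)) {
    stop("duplicated instance_id in annotations", call. = FALSE)
  }
  missing <- setdiff(instances, ann$instance_id)
  if (length(missing)) {
    stop("instances without annotation: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  ann[match(instances, ann$instance_id), need, drop = FALSE]
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Profile matrix:", length(x$genes), "genes x", length(x$instances),
      "instances;", if (x$is_ranks) "ranks" else "scores", "\n")
  if (!is.null(x$annotations)) {
    cat("  compounds:", length(unique(x$annotations$compound_id)),
        " cell lines:", length(unique(x$annotations$cell_line)), "\n")
  }
  invisible(x)
}

#' Write a profile matrix
#'
#' @param pm A `profile_matrix`.
#' @param path Output path; extension `.gct` selects GCT 1.2 (Description
#'   written as `"na"`), anything else plain TSV.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (tolower(tools::file_ext(path)) == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(length(pm$genes), length(pm$instances),
                               sep = "\t")), con)
    df <- data.frame(Name = pm$genes, Description = "na",
                     pm$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("Name", "Description", pm$instances)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(gene_id = pm$genes, pm$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", pm$instances)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an instance annotation table
#'
#' @param path TSV with mandatory header `instance_id`, `compound_id`,
#'   `cell_line`.
#' @return A data frame.
#' @export
read_instance_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("instance_id", "compound_id", "cell_line")
  if (!all(need %in% names(df))) {
    fmt_stop(path, "missing header columns ",
             paste(setdiff(need, names(df)), collapse = ", "))
  }
  df[need]
}

#' Write an instance annotation table
#' @param ann Data frame with `instance_id`, `compound_id`, `cell_line`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instance_annotations <- function(ann, path) {
  write.table(ann[c("instance_id", "compound_id", "cell_line")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' Tab-separated with mandatory header `source_gene`, `target_gene`.
#' One-to-many mappings (in either direction) are preserved as separate
#' rows; exact duplicate pairs are an error.
#'
#' @param path Path to the map.
#' @return A data frame of class `ortholog_map` with columns `source_gene`
#'   and `target_gene`.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("source_gene", "target_gene")
  if (!all(need %in% names(df))) {
    fmt_stop(path, "missing header columns ",
             paste(setdiff(need, names(df)), collapse = ", "))
  }
  ortholog_map(df[need])
}

#' Construct an ortholog map
#' @param pairs Data frame with character columns `source_gene`,
#'   `target_gene`; duplicate pairs are rejected.
#' @return The validated map with class `ortholog_map`.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("source_gene", "target_gene") %in% names(pairs)))
  if (anyDuplicated(pairs[c("source_gene", "target_gene")])) {
    stop("duplicate source/target pairs in ortholog map", call. = FALSE)
  }
  class(pairs) <- c("ortholog_map", "data.frame")
  pairs
}

#' Write an ortholog map
#' @param map An `ortholog_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(map[c("source_gene", "target_gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with mandatory header `gene_id`, `log2fc`, `p_adj`.
#' Gene ids must be unique, log2fc finite, and p_adj within \[0, 1\].
#'
#' @param path Path to the table.
#' @param contrast_label Label of the contrast (e.g. `"1dpi_vs_4hpi"`);
#'   defaults to the file name without extension.
#' @return A data frame of class `de_table` with attribute
#'   `contrast_label`.
#' @export
read_de_table <- function(path, contrast_label = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "log2fc", "p_adj")
  if (!all(need %in% names(df))) {
    fmt_stop(path, "missing header columns ",
             paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[need]
  if (!is.numeric(df$log2fc) || !is.numeric(df$p_adj)) {
    fmt_stop(path, "log2fc and p_adj must be numeric")
  }
  if (is.null(contrast_label)) {
    contrast_label <- tools::file_path_sans_ext(basename(path))
  }
  tryCatch(
    de_table(df, contrast_label),
    error = function(e) fmt_stop(path, conditionMessage(e))
  )
}

#' Construct a differential-expression table
#' @param df Data frame with columns `gene_id`, `log2fc`, `p_adj`.
#' @param contrast_label Contrast label stored as an attribute.
#' @return The validated table with class `de_table`.
#' @export
de_table <- function(df, contrast_label) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "log2fc", "p_adj") %in% names(df)))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicated gene_id (first: ", df$gene_id[duplicated(df$gene_id)][[1]],
         ")", call. = FALSE)
  }
  if (any(!is.finite(df$log2fc))) stop("log2fc must be finite", call. = FALSE)
  if (any(is.na(df$p_adj) | df$p_adj < 0 | df$p_adj > 1)) {
    stop("p_adj must lie in [0, 1]", call. = FALSE)
  }
  attr(df, "contrast_label") <- contrast_label
  class(df) <- c("de_table", "data.frame")
  df
}

#' Write a differential-expression table
#' @param de A `de_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(as.data.frame(de)[c("gene_id", "log2fc", "p_adj")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an integrated results table
#'
#' Header-first tab-separated table with fixed column order: compound,
#' direction, per-signature combined p-values, per-signature ranks, the
#' meta rank product, integrated p, BH q, and final rank.
#'
#' @param results An integrated results data frame from
#'   [integrate_signatures()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  fixed_head <- c("compound_id", "direction")
  fixed_tail <- c("meta_rp", "p_integrated", "q_fdr", "final_rank")
  p_cols <- grep("^p__", names(results), value = TRUE)
  rho_cols <- grep("^rho__", names(results), value = TRUE)
  cols <- c(fixed_head, p_cols, rho_cols, fixed_tail)
  missing <- setdiff(cols, names(results))
  if (length(missing)) {
    stop("results table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  write.table(results[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
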