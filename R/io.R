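#' Read a sample design table
#'
#' Tab-delimited file with columns `sample_id`, `stage`, `treatment`,
#' `replicate`.
#'
#' @param path file path.
#' @return A [sample_design()] table.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("sample_id", "stage", "treatment", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file lacks column(s): ", paste(miss, collapse = ", "))
  sample_design(d$sample_id, d$stage, d$treatment, d$replicate)
}

#' Read an expression table
#'
#' Ingests a tab-delimited quantification table (MaxQuant
#' proteinGroups-like: one row per feature, one intensity column per
#' sample) together with a design file mapping column names to samples.
#' Blank or zero cells are recorded as undetected. Sample columns are
#' matched by exact name — `value_prefix` is prepended to each
#' `sample_id` to form the expected column header (use `""` when headers
#' are the bare sample ids).
#'
#' @param path expression table path (TSV; feature-id column named by
#'   `id_column`).
#' @param design_path design table path (see [read_design()]).
#' @param value_prefix prefix of the per-sample intensity columns, e.g.
#'   `"iBAQ "`.
#' @param id_column name of the feature-id column (default first column).
#' @param modality `"protein"` or `"transcript"`.
#' @return A linear-scale [expr_matrix()].
#' @export
read_expression_table <- function(path, design_path, value_prefix = "",
                                  id_column = NULL,
                                  modality = c("protein", "transcript")) {
  modality <- match.arg(modality)
  design <- read_design(design_path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  if (is.null(id_column)) id_column <- names(tab)[1L]
  if (!id_column %in% names(tab))
    stop("feature-id column '", id_column, "' not found")
  ids <- tab[[id_column]]
  if (anyDuplicated(ids))
    stop("duplicated feature id: ", ids[duplicated(ids)][1L])
  want <- paste0(value_prefix, design$sample_id)
  miss <- setdiff(want, names(tab))
  if (length(miss))
    stop("sample column(s) not found in expression table: ",
         paste(miss, collapse = ", "))
  raw <- tab[, want, drop = FALSE]
  vals <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    empty <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                   cell[bad[1L]], bad[1L], want[j]))
    num[empty] <- 0
    vals[, j] <- num
  }
  dimnames(vals) <- list(ids, design$sample_id)
  expr_matrix(vals, design, scale = "linear", modality = modality)
}

#' Write an expression table
#'
#' Tab-delimited, fixed column order (`feature_id` then the samples in
#' design order), `.` decimal separator, full precision (17 significant
#' digits) so that a write/read round trip is bit-identical. Undetected
#' cells are written as empty strings on log scales and as `0` on the
#' linear scale.
#'
#' @param x an [expr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  v <- x$values
  out <- matrix("", nrow(v), ncol(v))
  det <- x$detected
  out[det] <- formatC(v[det], format = "g", digits = 17)
  if (x$scale == "linear") out[!det] <- "0"
  df <- data.frame(feature_id = rownames(v), out,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("feature_id", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a design table
#'
#' @param design a [sample_design()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  d <- data.frame(sample_id = design$sample_id,
                  stage = as.character(design$stage),
                  treatment = as.character(design$treatment),
                  replicate = design$replicate)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One term per line: term id, description, then tab-separated member
#' ids. Duplicate members within a term are removed with a warning.
#'
#' @param path GMT file path.
#' @return An object of class `gene_set_collection`: a named list of
#'   character vectors with a `description` attribute per term.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate member(s) in term '", f[1L], "' deduplicated")
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
    descs[f[1L]] <- f[2L]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d term(s), median size %s\n",
              length(x),
              if (length(x)) stats::median(lengths(x)) else "NA"))
  invisible(x)
}

## internal: recursive Newick string for an hclust merge entry.
## Branch length of a node = parent merge height - own height
## (leaves sit at height 0), so two leaves merged at height h get
## branch length h each.
.newick_node <- function(hc, node, parent_height) {
  if (node < 0) {  # leaf
    lab <- hc$labels[-node]
    sprintf("%s:%s", lab,
            sprintf("%.15g", parent_height))
  } else {
    h <- hc$height[node]
    left <- .newick_node(hc, hc$merge[node, 1L], h)
    right <- .newick_node(hc, hc$merge[node, 2L], h)
    sprintf("(%s,%s):%s", left, right,
            sprintf("%.15g", parent_height - h))
  }
}

#' Serialize a dendrogram as Newick
#'
#' Writes an `hclust` tree (e.g. from [hierarchical_cluster()]) as a
#' Newick string with branch lengths equal to the difference between the
#' parent's and the child's merge height; leaves sit at height zero, so
#' two leaves merged at height 1 serialize as `(A:1,B:1);`.
#'
#' @param tree an `hclust` object with unique labels.
#' @param path output file path, or `NULL` to return the string.
#' @return The Newick string, invisibly if written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust object")
  if (anyDuplicated(tree$labels))
    stop("duplicate leaf label: ",
         tree$labels[duplicated(tree$labels)][1L])
  n <- length(tree$labels)
  s <- if (n == 1L) {
    paste0(tree$labels, ";")
  } else {
    root <- nrow(tree$merge)
    h <- tree$height[root]
    left <- .newick_node(tree, tree$merge[root, 1L], h)
    right <- .newick_node(tree, tree$merge[root, 2L], h)
    sprintf("(%s,%s);", left, right)
  }
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
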