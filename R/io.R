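# Readers/writers for the flat-file formats the pipeline touches: TSV count
# tables (QIIME2 "#OTU ID" dialect tolerated), newick trees, metadata TSV,
# taxonomy TSV, and the harmonization step that reconciles the three.

#' Read an ASV/OTU count table from TSV
#'
#' The first column holds ids; a leading `#OTU ID` header cell (the QIIME2
#' flat-table dialect) or comment lines before the header are tolerated.
#' Cells must be non-negative integers.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"taxa_rows"` (default) if rows are taxa, or
#'   `"samples_rows"` if rows are samples; the returned matrix is always
#'   taxa x samples.
#' @return validated count matrix (taxa rows, sample columns).
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) ea_stop("empty count table file: ", path,
                              class = "ecoassembly_format_error")
  # Skip pure comment lines, but keep a "#OTU ID..." header.
  is_comment <- startsWith(lines, "#") & !grepl("^#OTU ID\t", lines)
  lines <- lines[!is_comment]
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_exp <- length(header)
  if (any(lengths(body) != ncol_exp))
    ea_stop("ragged rows in count table: ", path,
            class = "ecoassembly_format_error")
  ids <- trimws(vapply(body, `[[`, "", 1L))
  cells <- lapply(body, function(r) r[-1L])
  mat <- do.call(rbind, lapply(cells, function(r) {
    v <- suppressWarnings(as.numeric(r))
    v
  }))
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    ea_stop("non-integer or negative count at row ", bad[1, 1] + 1L,
            ", column ", bad[1, 2] + 1L, " of ", path,
            class = "ecoassembly_format_error")
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  colnames(mat) <- trimws(header[-1L])
  if (orientation == "samples_rows") mat <- t(mat)
  validate_count_table(mat)
  mat
}

#' Write a count table as TSV (QIIME2 flat dialect)
#'
#' @param table count matrix (taxa rows).
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(`#OTU ID` = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from newick
#'
#' Branch lengths absent in the file are set to 0 with a warning; duplicate
#' leaf labels are an error. Leaf labels are the taxon ids used to match
#' the count table.
#'
#' @param path newick file path.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) ea_stop("unparseable newick: ",
                                               conditionMessage(e),
                                               class = "ecoassembly_format_error"))
  if (is.null(tree)) ea_stop("unparseable newick file: ", path,
                             class = "ecoassembly_format_error")
  check_ids(tree$tip.label, "leaf")
  if (is.null(tree$edge.length)) {
    ea_warn("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    ea_warn("missing branch lengths in tree; treating them as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    ea_stop("negative branch length in tree", class = "ecoassembly_format_error")
  tree
}

#' Patristic distance matrix of a tree's leaves
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix of path-length distances between leaves.
#' @export
patristic_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Read sample metadata from TSV
#'
#' See [validate_metadata()] for the required columns and vocabularies.
#' Extra columns are preserved. Empty chemistry/coordinate cells become
#' `NA` and the sample is retained.
#'
#' @param path TSV path.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE, na.strings = c("", "NA"))
  for (v in c("latitude", "longitude", chemistry_vars))
    if (v %in% names(meta)) meta[[v]] <- as.numeric(meta[[v]])
  for (v in c("sample_id", "farm_id", "niche", "health"))
    if (v %in% names(meta)) meta[[v]] <- trimws(as.character(meta[[v]]))
  validate_metadata(meta)
  meta
}

#' Write sample metadata as TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table (taxon id + semicolon-delimited lineage)
#'
#' @param path TSV path with two columns: taxon id, lineage string such as
#'   `"Bacteria;Proteobacteria;..."` (at most 7 ranks, domain..genus+).
#' @return named list mapping taxon id to a character vector of ranks.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, header = TRUE)
  ids <- check_ids(df[[1]], "taxon")
  lineages <- strsplit(as.character(df[[2]]), ";", fixed = TRUE)
  lineages <- lapply(lineages, function(x) {
    x <- trimws(x)
    x[x == ""] <- "unclassified"
    if (length(x) > 7) ea_stop("lineage with more than 7 ranks",
                               class = "ecoassembly_format_error")
    x
  })
  setNames(lineages, ids)
}

#' Reconcile count table, tree and metadata to a shared id set
#'
#' Under `policy = "intersect"` the table is restricted to taxa present as
#' tree leaves and samples present in the metadata, the tree is pruned to
#' the surviving taxa, and all-zero rows/columns are dropped (a message
#' reports how many). Under `policy = "strict"` any mismatch is an error.
#' The operation is idempotent.
#'
#' @param table count matrix (taxa rows).
#' @param tree `phylo` tree whose tips are taxon ids.
#' @param meta metadata data.frame.
#' @param policy `"intersect"` or `"strict"`.
#' @return list with elements `table`, `tree`, `meta`.
#' @export
harmonize <- function(table, tree, meta, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  validate_count_table(table)
  validate_metadata(meta)
  taxa <- intersect(rownames(table), tree$tip.label)
  samples <- intersect(colnames(table), meta$sample_id)
  if (policy == "strict") {
    lost_taxa <- setdiff(rownames(table), tree$tip.label)
    lost_samp <- setdiff(colnames(table), meta$sample_id)
    if (length(lost_taxa))
      ea_stop("taxa absent from tree: ", paste(lost_taxa, collapse = ", "),
              class = "ecoassembly_mismatch_error")
    if (length(lost_samp))
      ea_stop("samples absent from metadata: ", paste(lost_samp, collapse = ", "),
              class = "ecoassembly_mismatch_error")
  }
  if (!length(taxa) || !length(samples))
    ea_stop("empty intersection of ids between table, tree and metadata",
            class = "ecoassembly_mismatch_error")
  tab <- table[taxa, samples, drop = FALSE]
  zero_rows <- rowSums(tab) == 0
  zero_cols <- colSums(tab) == 0
  if (any(zero_rows) || any(zero_cols))
    message("harmonize: dropping ", sum(zero_rows), " all-zero taxa and ",
            sum(zero_cols), " all-zero samples")
  tab <- tab[!zero_rows, !zero_cols, drop = FALSE]
  if (!nrow(tab) || !ncol(tab))
    ea_stop("no taxa or samples survive harmonization",
            class = "ecoassembly_mismatch_error")
  keep_taxa <- rownames(tab)
  pruned <- if (length(setdiff(tree$tip.label, keep_taxa)))
    ape::keep.tip(tree, keep_taxa) else tree
  meta2 <- meta[match(colnames(tab), meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  list(table = tab, tree = pruned, meta = meta2)
}
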