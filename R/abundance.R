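#' Samples-by-taxa abundance table
#'
#' Integer 16S count matrix (rows = samples, columns = genus-level taxa)
#' with a taxonomy map assigning every taxon to exactly one phylum, and an
#' optional link to the rooted taxonomic tree the taxa were pruned from.
#'
#' @param counts integer matrix, samples x taxa, with dimnames.
#' @param taxonomy named character vector: taxon -> phylum, or a data.frame
#'   with columns `taxon` and `phylum` (extra rank columns are kept).
#' @param tree optional `phylo` whose tip labels are the taxon ids.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy, tree = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop_invalid("abundance table has 0 samples")
  if (is.null(colnames(counts))) stop_invalid("counts must have taxon column names")
  if (anyDuplicated(colnames(counts))) {
    stop_invalid("duplicate taxon ids: %s",
                 paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                       collapse = ", "))
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop_invalid("non-integer or negative count at row %d, column %d", bad[1], bad[2])
  }
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max sums
  if (is.data.frame(taxonomy)) {
    tax_map <- setNames(as.character(taxonomy$phylum), taxonomy$taxon)
  } else {
    tax_map <- taxonomy
  }
  missing_tax <- setdiff(colnames(counts), names(tax_map))
  if (length(missing_tax)) {
    stop_invalid("taxa without phylum assignment: %s",
                 paste(missing_tax, collapse = ", "))
  }
  structure(list(counts = counts,
                 taxonomy = tax_map[colnames(counts)],
                 tree = tree),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d samples x %d taxa (%d phyla)%s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$taxonomy)),
              if (!is.null(x$tree)) ", tree attached" else ""))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Read a counts TSV into an abundance table
#'
#' Expects a header of taxon names with the first column holding sample
#' ids. Taxon names may be semicolon-delimited lineage strings
#' (`...;p__Firmicutes;...;g__Blautia`); the phylum is then parsed from the
#' `p__` field and the genus field becomes the taxon id. Plain genus names
#' require a separate `taxonomy` argument or a tree with phylum labels.
#'
#' @param path TSV path.
#' @param taxonomy optional named phylum map for plain genus headers.
#' @param tree optional `phylo`; if it carries `p__` node labels, phyla are
#'   recovered from it (see [genus_phyla()]).
#' @return an `abundance_table`.
#' @export
read_counts <- function(path, taxonomy = NULL, tree = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_invalid("empty counts table: %s", path)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_invalid("non-numeric count at row %d, column '%s'",
                 bad[1], colnames(mat)[bad[2]])
  }
  if (any(mat != round(mat))) {
    bad <- which(mat != round(mat), arr.ind = TRUE)[1, ]
    stop_invalid("non-integer count at row %d, column '%s'",
                 bad[1], colnames(mat)[bad[2]])
  }
  rownames(mat) <- ids
  cn <- colnames(mat)
  if (all(grepl(";", cn))) {
    phyla <- sub("^.*p__([^;]+);.*$", "\\1", cn)
    genera <- sub("^.*g__", "", cn)
    colnames(mat) <- genera
    taxonomy <- setNames(phyla, genera)
  } else if (is.null(taxonomy) && !is.null(tree)) {
    taxonomy <- genus_phyla(tree)
  }
  if (is.null(taxonomy)) stop_invalid("no taxonomy available for plain genus headers")
  abundance_table(mat, taxonomy, tree)
}

#' Write an abundance table to TSV
#'
#' Column headers are full lineage strings (`k__Bacteria;p__<phylum>;g__<genus>`)
#' so the phylum map round-trips through [read_counts()].
#'
#' @param table an `abundance_table`.
#' @param path output TSV path.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  hdr <- sprintf("k__Bacteria;p__%s;g__%s", table$taxonomy, colnames(table$counts))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  colnames(df)[-1] <- hdr
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recover the phylum of every genus leaf from tree node labels
#'
#' Each leaf's phylum is the `p__`-prefixed label of its nearest labeled
#' ancestor, the convention used by [sim_tax_tree()].
#'
#' @param tree a rooted `phylo` with `p__<Phylum>` internal node labels.
#' @return named character vector: genus -> phylum.
#' @export
genus_phyla <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  labs <- c(rep(NA_character_, n_tip), tree$node.label %||% character(0))
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_len(n_tip), function(tip) {
    node <- tip
    while (!is.na(node)) {
      if (!is.na(labs[node]) && startsWith(labs[node], "p__")) {
        return(sub("^p__", "", labs[node]))
      }
      node <- parent[node]
    }
    NA_character_
  }, character(1)) -> phyla
  setNames(phyla, tree$tip.label)
}
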