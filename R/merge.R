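# Two-stage phylogeny-guided aggregation of genus counts into taxonomic
# groups. Stage 1 merges rare nodes into their nearest neighbor, summing
# counts; stage 2 merges correlated sibling groups, averaging counts.
# Merging only ever joins neighboring nodes of the (dynamically collapsed)
# taxonomic tree.

# -- internal mutable tree state ---------------------------------------------

# Build the collapsed-tree engine state from a phylo and a counts matrix
# whose columns are the tip labels.
merge_state_new <- function(counts, tree) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- colnames(counts)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop_invalid("taxa absent from the tree: %s", paste(missing, collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  parent <- integer(n_node)           # 0 = root
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    parent[b] <- a
    children[[a]] <- c(children[[a]], b)
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  active <- rep(TRUE, n_node)
  # drop tips not present in the counts (pruned upstream), then collapse
  unit_of <- rep(NA_integer_, n_node)
  units <- vector("list", n_tip)
  for (tip in seq_len(n_tip)) {
    g <- tree$tip.label[tip]
    if (g %in% taxa) {
      unit_of[tip] <- tip
      units[[tip]] <- list(members = g, counts = counts[, g], name = g,
                           node = tip, alive = TRUE)
    }
  }
  st <- new.env(parent = emptyenv())
  st$parent <- parent; st$children <- children; st$active <- active
  st$root <- root; st$unit_of <- unit_of; st$units <- units
  st$audit <- list(); st$n_tip <- n_tip
  # remove tips without counts
  for (tip in seq_len(n_tip)) {
    if (is.na(unit_of[tip])) state_remove_node(st, tip)
  }
  st
}

# Splice out internal nodes left with a single child (and a single-child root).
state_collapse <- function(st, node) {
  while (node != 0L && st$active[node] && is.na(st$unit_of[node])) {
    kids <- st$children[[node]]
    kids <- kids[st$active[kids]]
    st$children[[node]] <- kids
    if (length(kids) != 1L) break
    child <- kids
    p <- st$parent[node]
    st$active[node] <- FALSE
    st$parent[child] <- p
    if (p == 0L) {
      st$root <- child
    } else {
      st$children[[p]][st$children[[p]] == node] <- child
    }
    node <- p
  }
}

state_remove_node <- function(st, node) {
  p <- st$parent[node]
  st$active[node] <- FALSE
  if (p != 0L) {
    st$children[[p]] <- setdiff(st$children[[p]], node)
    state_collapse(st, p)
  } else {
    kids <- st$children[[node]]
    kids <- kids[st$active[kids]]
    if (length(kids) == 1L) { st$root <- kids; st$parent[kids] <- 0L }
  }
}

# Active unit nodes in post-order (left-to-right leaf order of the
# collapsed tree) — the deterministic traversal order for rule firing.
state_unit_order <- function(st) {
  out <- integer(0)
  walk <- function(node) {
    if (!st$active[node]) return(invisible())
    if (!is.na(st$unit_of[node])) {
      out[[length(out) + 1L]] <<- node
    } else {
      for (k in st$children[[node]]) if (st$active[k]) walk(k)
    }
  }
  walk(st$root)
  out
}

state_depth <- function(st, node) {
  d <- 0L
  while (st$parent[node] != 0L) { node <- st$parent[node]; d <- d + 1L }
  d
}

# Path distance (edge count) between two active nodes via their ancestor
# chains.
state_dist <- function(st, a, b) {
  anc <- function(node) {
    path <- node
    while (st$parent[node] != 0L) { node <- st$parent[node]; path <- c(path, node) }
    path
  }
  pa <- anc(a); pb <- anc(b)
  common <- intersect(pa, pb)[1]
  (match(common, pa) - 1L) + (match(common, pb) - 1L)
}

# Nearest other unit to `node`: minimal path distance in the collapsed
# tree; ties broken by traversal (branch-order) index, then by name.
state_nearest_unit <- function(st, node) {
  ord <- state_unit_order(st)
  others <- setdiff(ord, node)
  if (!length(others)) return(NA_integer_)
  d <- vapply(others, function(o) state_dist(st, node, o), 1L)
  cand <- others[d == min(d)]
  if (length(cand) > 1L) {
    idx <- match(cand, ord)
    nm <- vapply(cand, function(o) st$units[[st$unit_of[o]]]$name, "")
    cand <- cand[order(idx, nm)]
  }
  cand[1]
}

# Merge the unit at node_a into the unit at node_b.
# combine = "sum" (stage 1) or "mean" (stage 2).
state_merge_units <- function(st, node_a, node_b, combine, rule, statistic) {
  ua <- st$units[[st$unit_of[node_a]]]
  ub <- st$units[[st$unit_of[node_b]]]
  st$audit[[length(st$audit) + 1L]] <- data.frame(
    stage = if (combine == "sum") 1L else 2L,
    unit_a = ua$name, unit_b = ub$name, rule = rule,
    statistic = statistic, stringsAsFactors = FALSE)
  ub$members <- c(ub$members, ua$members)
  ub$counts <- if (combine == "sum") ub$counts + ua$counts
               else (ub$counts + ua$counts) / 2
  ub$name <- paste0(ub$name, "+", ua$name)
  st$units[[st$unit_of[node_b]]] <- ub
  st$units[[st$unit_of[node_a]]]$alive <- FALSE
  st$unit_of[node_a] <- NA_integer_
  state_remove_node(st, node_a)
  invisible(st)
}

# Promote a unit to its parent when it is the parent's only surviving
# child (handled by collapse), keeping the unit attached to `node_b`.

# -- stage drivers ------------------------------------------------------------

is_rare <- function(counts, min_count, prevalence, n_samples) {
  sum(counts < min_count) > prevalence * n_samples
}

run_stage1 <- function(st, min_count, prevalence) {
  n_samples <- length(st$units[[st$unit_of[state_unit_order(st)[1]]]]$counts)
  repeat {
    ord <- state_unit_order(st)
    if (length(ord) <= 1L) break
    fired <- FALSE
    for (node in ord) {
      u <- st$units[[st$unit_of[node]]]
      if (is_rare(u$counts, min_count, prevalence, n_samples)) {
        target <- state_nearest_unit(st, node)
        if (is.na(target)) break
        state_merge_units(st, node, target, "sum", "rarity",
                          sum(u$counts < min_count))
        fired <- TRUE
        break     # re-derive traversal: merged sums can enter/exit rarity
      }
    }
    if (!fired) break
  }
  invisible(st)
}

run_stage2 <- function(st, r_threshold) {
  repeat {
    ord <- state_unit_order(st)
    if (length(ord) <= 1L) break
    fired <- FALSE
    for (node in ord) {
      p <- st$parent[node]
      if (p == 0L) next
      sibs <- st$children[[p]]
      sibs <- sibs[st$active[sibs] & !is.na(st$unit_of[sibs]) & sibs != node]
      if (!length(sibs)) next
      # deterministic sibling order: branch order then name
      nm <- vapply(sibs, function(s) st$units[[st$unit_of[s]]]$name, "")
      sibs <- sibs[order(match(sibs, st$children[[p]]), nm)]
      a <- st$units[[st$unit_of[node]]]$counts
      for (s in sibs) {
        b <- st$units[[st$unit_of[s]]]$counts
        if (sd(a) == 0 || sd(b) == 0) next  # undefined r: not mergeable, logged
        r <- cor(a, b)
        if (r > r_threshold) {
          state_merge_units(st, s, node, "mean", "correlation", r)
          fired <- TRUE
          break
        }
      }
      if (fired) break
    }
    if (!fired) break
  }
  invisible(st)
}

# -- result assembly ----------------------------------------------------------

finalize_merge <- function(st, taxonomy, params) {
  ord <- state_unit_order(st)
  members <- lapply(ord, function(n) sort(st$units[[st$unit_of[n]]]$members))
  counts <- vapply(ord, function(n) st$units[[st$unit_of[n]]]$counts,
                   numeric(length(st$units[[st$unit_of[ord[1]]]]$counts)))
  counts <- matrix(counts, ncol = length(ord))
  # group ids: single member keeps the genus name; multi-member groups take
  # the members' lowest common rank (phylum here) plus a stable index
  ids <- character(length(ord))
  k <- 0L
  for (i in seq_along(ord)) {
    mem <- members[[i]]
    if (length(mem) == 1L) {
      ids[i] <- mem
    } else {
      k <- k + 1L
      ph <- unique(taxonomy[mem])
      ids[i] <- sprintf("%s_grp%02d", if (length(ph) == 1L) ph else "Bacteria", k)
    }
  }
  colnames(counts) <- ids
  rownames(counts) <- names(st$units[[st$unit_of[ord[1]]]]$counts)
  audit <- if (length(st$audit)) do.call(rbind, st$audit) else
    data.frame(stage = integer(0), unit_a = character(0), unit_b = character(0),
               rule = character(0), statistic = numeric(0))
  structure(list(groups = setNames(members, ids), matrix = counts,
                 audit = audit, params = params),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  multi <- sum(lengths(x$groups) > 1L)
  cat(sprintf("Taxonomic merge: %d genera -> %d groups (%d multi-genus, %d singleton)\n",
              sum(lengths(x$groups)), length(x$groups), multi,
              length(x$groups) - multi))
  if (nrow(x$audit)) {
    cat(sprintf("  stage 1 (rarity, counts summed): %d merges\n",
                sum(x$audit$stage == 1L)))
    cat(sprintf("  stage 2 (correlation > %.2f, counts averaged): %d merges\n",
                x$params$r_threshold %||% NA, sum(x$audit$stage == 2L)))
  } else cat("  no merges fired\n")
  invisible(x)
}

# -- exported operations ------------------------------------------------------

#' Stage 1: merge low-abundance taxa into tree neighbors
#'
#' Moving upward along the taxonomic tree, a node whose abundance is below
#' `min_count` in strictly more than `prevalence` of the samples is merged
#' into its nearest neighboring node (sibling group, ties broken by branch
#' order then name) and the counts are summed. The rule is re-checked
#' after every merge until no node fires.
#'
#' @param table an `abundance_table` whose taxa are tree leaves.
#' @param tree rooted `phylo`; defaults to the tree attached to `table`.
#' @param min_count rarity count threshold (default 5).
#' @param prevalence rarity prevalence threshold (default 0.90).
#' @return a `merge_state` (pass to [merge_correlated()]); its
#'   `$result` holds the stage-1 `merge_result` and `$matrix` the merged
#'   counts.
#' @export
merge_low_abundance <- function(table, tree = NULL, min_count = 5,
                                prevalence = 0.90) {
  stopifnot(inherits(table, "abundance_table"))
  tree <- tree %||% table$tree
  if (is.null(tree)) stop_invalid("no tree supplied or attached to the table")
  st <- merge_state_new(table$counts, tree)
  run_stage1(st, min_count, prevalence)
  params <- list(min_count = min_count, prevalence = prevalence)
  res <- finalize_merge(st, table$taxonomy, params)
  structure(list(state = st, taxonomy = table$taxonomy, params = params,
                 result = res, matrix = res$matrix),
            class = "merge_state")
}

#' Stage 2: merge correlated sibling groups
#'
#' Moving upward from the stage-1 output, sibling groups whose abundances
#' have Pearson correlation above `r_threshold` across samples are merged
#' and their counts element-wise averaged, repeated to a fixpoint.
#' Constant (e.g. all-zero) columns have undefined correlation and are
#' never merged by this rule.
#'
#' @param x a `merge_state` from [merge_low_abundance()], or an
#'   `abundance_table` (stage 2 alone on unmerged genera).
#' @param tree tree when `x` is an `abundance_table`.
#' @param r_threshold correlation threshold (default 0.7).
#' @return a `merge_result` covering all merges so far.
#' @export
merge_correlated <- function(x, tree = NULL, r_threshold = 0.7) {
  if (inherits(x, "abundance_table")) {
    tree <- tree %||% x$tree
    st <- merge_state_new(x$counts, tree)
    taxonomy <- x$taxonomy
    params <- list(r_threshold = r_threshold)
  } else if (inherits(x, "merge_state")) {
    st <- x$state
    taxonomy <- x$taxonomy
    params <- c(x$params, list(r_threshold = r_threshold))
  } else stop_invalid("x must be an abundance_table or merge_state")
  run_stage2(st, r_threshold)
  finalize_merge(st, taxonomy, params)
}

#' Two-stage phylogeny-guided taxon aggregation
#'
#' Composition of [merge_low_abundance()] (rare nodes merged into
#' neighbors, counts summed) and [merge_correlated()] (correlated sibling
#' groups merged, counts averaged). Tailors the taxonomic resolution to
#' the data: scarcely observed or collinear branches are lumped, abundant
#' and independently varying branches keep genus-level resolution.
#'
#' @inheritParams merge_low_abundance
#' @param r_threshold stage-2 correlation threshold (default 0.7).
#' @return a `merge_result`: `groups` (partition of the genera), `matrix`
#'   (samples x groups, real-valued after stage-2 averaging), `audit`
#'   (ordered merge log with the rule fired and its statistic).
#' @export
merge_taxa <- function(table, tree = NULL, min_count = 5, prevalence = 0.90,
                       r_threshold = 0.7) {
  s1 <- merge_low_abundance(table, tree, min_count, prevalence)
  merge_correlated(s1, r_threshold = r_threshold)
}

#' Write merge outputs
#'
#' Merged matrix as TSV, group membership as JSON, audit log as TSV.
#'
#' @param result a `merge_result`.
#' @param dir output directory.
#' @export
write_merge_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(sample_id = rownames(result$matrix), result$matrix,
                   check.names = FALSE)
  write.table(df, file.path(dir, "merged_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$groups, file.path(dir, "groups.json"))
  write.table(result$audit, file.path(dir, "merge_audit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
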