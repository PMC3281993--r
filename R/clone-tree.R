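#' Build the clonal genealogy of a genotype set
#'
#' Under the infinite-sites assumption every somatic marker arose exactly
#' once, so the distinct genotypes of a clonally transmitted cancer admit a
#' *perfect phylogeny* rooted at the all-ancestral genotype: the carrier
#' sets of the markers form a laminar family (any two are nested or
#' disjoint). Each pair of markers is checked with the rooted
#' three-gamete test; a conflict-free matrix yields the unique perfect
#' phylogeny, with each edge labelled by the markers gained along it and
#' weighted by their number. Conflicting matrices are repaired greedily by
#' duplicating the rarer marker of each conflicting pair (maximum-parsimony
#' style), and the number of duplications is reported as the homoplasy
#' count.
#'
#' @param genotypes A [collapse_genotypes()] result, or a raw genotype
#'   matrix (collapsed internally). Missing calls are treated as ancestral
#'   (0) for tree building.
#' @return An object of class `clone_tree`: list with `nodes` (tibble:
#'   `node`, `parent`, `genotype_id`, `n_tumors`, list-columns `markers`
#'   -- full path marker set -- and `tumor_ids`), `edges` (tibble:
#'   `parent`, `node`, `weight`, list-column `markers_gained`),
#'   `conflicts` (tibble of conflicting marker pairs found),
#'   `homoplasy` (number of marker duplications applied). The root node
#'   `"root"` is the all-ancestral genotype.
#' @export
build_clone_tree <- function(genotypes) {
  if (!inherits(genotypes, "genotype_table")) {
    genotypes <- collapse_genotypes(genotypes)
  }
  if (nrow(genotypes) == 0L) abort("empty genotype table")
  markers_all <- attr(genotypes, "markers_all")
  pat <- do.call(rbind, lapply(genotypes$pattern, function(p) {
    p[is.na(p)] <- 0L
    p
  }))
  rownames(pat) <- genotypes$genotype_id
  # weight carrier counts by genotype (not tumour) multiplicity
  seg <- colSums(pat) > 0
  pat <- pat[, seg, drop = FALSE]

  conflicts <- detect_marker_conflicts(pat)
  homoplasy <- 0L
  while (nrow(cc <- detect_marker_conflicts(pat)) > 0) {
    # duplicate the rarer marker of the first conflicting pair
    m1 <- cc$marker1[1]; m2 <- cc$marker2[1]
    rare <- if (sum(pat[, m1]) <= sum(pat[, m2])) m1 else m2
    other <- if (rare == m1) m2 else m1
    inside <- pat[, rare] == 1 & pat[, other] == 1
    outside <- pat[, rare] == 1 & pat[, other] == 0
    pat <- cbind(pat[, colnames(pat) != rare, drop = FALSE],
                 matrix(as.integer(inside), ncol = 1,
                        dimnames = list(NULL, paste0(rare, "&", other))),
                 matrix(as.integer(outside), ncol = 1,
                        dimnames = list(NULL, paste0(rare, "!", other))))
    empty <- colSums(pat) == 0
    pat <- pat[, !empty, drop = FALSE]
    homoplasy <- homoplasy + 1L
  }

  tree <- perfect_phylogeny_trie(pat)
  members <- tibble(key = tree$terminal,
                    genotype_id = genotypes$genotype_id,
                    n_tumors = genotypes$n_tumors,
                    tumor_ids = genotypes$tumor_ids) |>
    group_by(.data$key) |>
    summarise(genotype_id = paste(.data$genotype_id, collapse = ","),
              n_tumors = sum(.data$n_tumors),
              tumor_ids = list(unlist(.data$tumor_ids, use.names = FALSE)),
              .groups = "drop")
  nodes <- tree$nodes |>
    left_join(members, by = "key") |>
    mutate(n_tumors = tidyr::replace_na(.data$n_tumors, 0L))
  out <- list(nodes = nodes, edges = tree$edges,
              conflicts = conflicts, homoplasy = homoplasy,
              markers = colnames(pat))
  class(out) <- "clone_tree"
  out
}

# Rooted three-gamete test: with an all-zero root, markers i and j conflict
# iff carriers overlap without nesting, i.e. patterns (1,1), (1,0) and (0,1)
# all occur.
detect_marker_conflicts <- function(pat) {
  m <- ncol(pat)
  rows <- list()
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        a <- pat[, i]; b <- pat[, j]
        if (any(a & b) && any(a & !b) && any(!a & b)) {
          rows[[length(rows) + 1L]] <- tibble(marker1 = colnames(pat)[i],
                                              marker2 = colnames(pat)[j])
        }
      }
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(marker1 = character(), marker2 = character())
}

# Gusfield-style trie construction of the unique perfect phylogeny of a
# conflict-free binary matrix rooted at the all-zero genotype, followed by
# compression of member-free unary chains into multi-marker edges.
perfect_phylogeny_trie <- function(pat) {
  order_markers <- colnames(pat)[order(-colSums(pat), colnames(pat))]
  node_key <- "root"          # keys are sorted marker-path strings
  parent <- c(root = NA_character_)
  gained <- list(root = character(0))
  terminal <- character(nrow(pat))
  for (r in seq_len(nrow(pat))) {
    path <- order_markers[pat[r, order_markers] == 1]
    cur <- "root"
    acc <- character(0)
    for (mk in path) {
      acc <- c(acc, mk)
      key <- paste(sort(acc), collapse = "|")
      if (!key %in% node_key) {
        node_key <- c(node_key, key)
        parent[key] <- cur
        gained[[key]] <- mk
      }
      cur <- key
    }
    terminal[r] <- cur
  }
  has_member <- node_key %in% terminal
  children <- split(node_key[-1], parent[node_key[-1]])
  # compress: absorb member-free nodes with a single child into that child's
  # incoming edge
  repeat {
    n_children <- vapply(node_key, function(k) {
      length(children[[k]] %||% character(0))
    }, integer(1))
    drop <- node_key != "root" & !has_member & n_children == 1L
    if (!any(drop)) break
    k <- node_key[drop][1]
    child <- children[[k]][1]
    gained[[child]] <- c(gained[[k]], gained[[child]])
    parent[child] <- parent[[k]]
    children[[parent[[k]]]] <-
      c(setdiff(children[[parent[[k]]]], k), child)
    children[[k]] <- NULL
    keep <- node_key != k
    node_key <- node_key[keep]
    has_member <- has_member[keep]
    parent <- parent[node_key]
  }
  nodes <- tibble(
    node = node_key,
    key = node_key,
    parent = unname(parent[node_key]),
    markers = lapply(node_key, function(k) {
      if (k == "root") character(0) else strsplit(k, "|", fixed = TRUE)[[1]]
    })
  )
  edges <- nodes |>
    filter(!is.na(.data$parent)) |>
    transmute(parent = .data$parent, node = .data$node,
              markers_gained = unname(gained[.data$node]),
              weight = lengths(.data$markers_gained))
  list(nodes = nodes, edges = edges, terminal = terminal)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf(
    "<clone_tree> %d nodes, %d edges, total weight %d, %d conflicting marker pairs (homoplasy %d)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$weight), nrow(x$conflicts),
    x$homoplasy))
  invisible(x)
}

#' @rdname build_clone_tree
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @export
tidy.clone_tree <- function(x, ...) x$edges

#' @rdname build_clone_tree
#' @export
glance.clone_tree <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    total_weight = sum(x$edges$weight),
    n_conflicts = nrow(x$conflicts),
    homoplasy = x$homoplasy
  )
}

#' Newick serialisation of a clone tree
#'
#' Branch lengths are the distinguishing-variant counts (edge weights);
#' node labels are genotype ids where a node carries tumours, otherwise the
#' internal node key.
#'
#' @param tree A `clone_tree`.
#' @return A single Newick string (rooted, with branch lengths).
#' @export
clone_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- tree$nodes
  edges <- tree$edges
  label <- ifelse(is.na(nodes$genotype_id),
                  gsub("[^A-Za-z0-9]", "_", nodes$node),
                  nodes$genotype_id)
  names(label) <- nodes$node
  kids <- split(edges$node, edges$parent)
  wt <- setNames(edges$weight, edges$node)
  rec <- function(k) {
    ch <- kids[[k]] %||% character(0)
    body <- if (length(ch)) {
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")")
    } else ""
    blen <- if (k == "root") "" else paste0(":", wt[[k]])
    paste0(body, label[[k]], blen)
  }
  paste0(rec("root"), ";")
}

#' Plot a clone tree
#'
#' Renders the genealogy via [ape::read.tree()] on the Newick serialisation;
#' branch lengths are distinguishing-variant counts.
#'
#' @param x A `clone_tree`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.clone_tree <- function(x, ...) {
  phy <- ape::read.tree(text = clone_tree_newick(x))
  ape::plot.phylo(phy, show.node.label = TRUE, ...)
  invisible(phy)
}
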