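## Rooted tree representation: nested lists. A leaf is list(leaf = "T1");
## an internal node is list(children = list(node, node)). The germline root
## is implicit: every topology over the lesions hangs, together with the
## germline leaf, from a top-level root node, so the edge above the lesion
## subtree is the trunk edge. Rooting an unrooted binary tree on
## k = n_lesions + 1 taxa at the germline leaf is a bijection onto rooted
## binary trees over the n lesions, so the (2k-5)!! count applies.

leaf_node <- function(label) list(leaf = label)
join_nodes <- function(a, b) list(children = list(a, b))
is_leaf <- function(node) !is.null(node$leaf)

## insert `taxon` above every edge of `tree` (including the stem edge)
insert_everywhere <- function(tree, taxon) {
  out <- list(join_nodes(tree, leaf_node(taxon)))  # stem edge
  if (!is_leaf(tree)) {
    for (i in seq_along(tree$children)) {
      for (sub in insert_everywhere(tree$children[[i]], taxon)) {
        t2 <- tree
        t2$children[[i]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

double_factorial <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

#' Enumerate candidate rooted topologies
#'
#' All distinct unrooted binary topologies on the germline taxon plus the
#' lesions, rooted at the germline; equivalently, all rooted binary trees over
#' the lesion set. The count for k taxa (germline included) is (2k-5)!!.
#' Exhaustive enumeration is the method of choice at this scale; heuristic
#' search for larger lesion sets is deliberately out of scope.
#'
#' @param lesions Character vector of lesion ids (the germline taxon is
#'   implicit); 2 to 7 lesions (3 to 8 taxa).
#' @return List of rooted topology objects (nested-list trees over the
#'   lesions).
#' @export
enumerate_topologies <- function(lesions) {
  n_taxa <- length(lesions) + 1L
  if (n_taxa < 3 || n_taxa > 8)
    stop("exhaustive search supports 3 to 8 taxa (2 to 7 lesions); ",
         "heuristic search is out of scope", call. = FALSE)
  trees <- list(leaf_node(lesions[1]))
  for (taxon in lesions[-1]) {
    trees <- unlist(lapply(trees, insert_everywhere, taxon = taxon),
                    recursive = FALSE)
  }
  stopifnot(length(trees) == double_factorial(2L * n_taxa - 5L))
  trees
}

## ---- parsimony scoring ----

## Flatten a lesion topology into parent/child arrays with the germline root.
## Node 1 = root (joins germline + lesion subtree); germline is node 2.
flatten_topology <- function(topology, lesions) {
  parent <- integer(0); label <- character(0); is_tip <- logical(0)
  add_node <- function(node, par) {
    id <- length(parent) + 1L
    parent[id] <<- par
    if (is_leaf(node)) {
      label[id] <<- node$leaf; is_tip[id] <<- TRUE
    } else {
      label[id] <<- NA_character_; is_tip[id] <<- FALSE
    }
    if (!is_leaf(node))
      for (ch in node$children) add_node(ch, id)
    id
  }
  ## root
  parent[1] <- 0L; label[1] <- NA_character_; is_tip[1] <- FALSE
  parent[2] <- 1L; label[2] <- "germline"; is_tip[2] <- TRUE
  add_node(topology, 1L)
  list(parent = parent, label = label, is_tip = is_tip,
       n = length(parent))
}

## Sankoff-style minimal changes for one binary character with the root state
## fixed at 0 (no somatic event precedes the germline). Among minimal-change
## labelings the one with the fewest losses is selected (losses only where
## strictly necessary), encoded by pricing a loss at 1 + eps with eps too
## small to trade against a whole change; remaining ties are broken towards
## the mutant state during the top-down pass, pulling gains onto the earliest
## (rootward) possible edge. Returns the unit-cost score and change edges
## (child node ids).
score_character <- function(flat, states) {
  n <- flat$n
  INF <- 1e9
  GAIN <- 1
  LOSS <- 1 + 1e-7
  trans <- function(s, t) if (s == t) 0 else if (t == 1L) GAIN else LOSS
  cost <- matrix(INF, n, 2)            # cost[node, state+1]
  for (v in seq(n, 1L)) {              # children have larger ids than parents
    if (flat$is_tip[v]) {
      s <- if (flat$label[v] == "germline") 0L else states[[flat$label[v]]]
      cost[v, s + 1L] <- 0
    } else {
      kids <- which(flat$parent == v)
      for (s in 0:1) {
        tot <- 0
        for (k in kids)
          tot <- tot + min(cost[k, 1] + trans(s, 0L), cost[k, 2] + trans(s, 1L))
        cost[v, s + 1L] <- tot
      }
    }
  }
  ## top-down backtrack from the fixed root state 0; ties -> state 1
  assign <- integer(n)
  assign[1] <- 0L
  gains <- integer(0); losses <- integer(0)
  for (v in seq(2L, n)) {
    par_state <- assign[flat$parent[v]]
    c0 <- cost[v, 1] + trans(par_state, 0L)
    c1 <- cost[v, 2] + trans(par_state, 1L)
    assign[v] <- if (c1 <= c0) 1L else 0L
    if (assign[v] != par_state) {
      if (assign[v] == 1L) gains <- c(gains, v) else losses <- c(losses, v)
    }
  }
  score <- length(gains) + length(losses)
  stopifnot(abs(cost[1, 1] - (length(gains) * GAIN + length(losses) * LOSS)) < 1e-4)
  list(score = score, gains = gains, losses = losses, states = assign)
}

#' Score a topology against an event matrix
#'
#' Computes the parsimony score of a rooted lesion topology for every event
#' (binary character) of an event matrix, with the germline root constrained
#' to state 0 (no somatic event precedes the germline). Among minimal
#' labelings, gains are placed as close to the root as possible, so a trunk
#' event lands on the edge incident to the root. Events are assigned to the
#' edges on which their state changes; the edge length is its change count.
#'
#' @param topology A rooted lesion topology from [enumerate_topologies()].
#' @param matrix An `event_matrix`.
#' @return List: `score` (total state changes), `edges` (data frame: edge id,
#'   parent, child, length, head label), `assignments` (data frame: event key,
#'   edge id, change type gain/loss). Characters with all-zero states cannot
#'   arise from [build_event_matrix()] and are rejected.
#' @export
score_tree <- function(topology, matrix) {
  flat <- flatten_topology(topology, matrix$lesions)
  n_events <- nrow(matrix$presence)
  gains_by_edge <- vector("list", flat$n)
  losses_by_edge <- vector("list", flat$n)
  total <- 0
  if (n_events > 0 && any(rowSums(matrix$presence) == 0))
    stop("character with all-zero states", call. = FALSE)
  for (i in seq_len(n_events)) {
    states <- as.list(as.integer(matrix$presence[i, ]))
    names(states) <- matrix$lesions
    res <- score_character(flat, states)
    total <- total + res$score
    for (v in res$gains)
      gains_by_edge[[v]] <- c(gains_by_edge[[v]], rownames(matrix$presence)[i])
    for (v in res$losses)
      losses_by_edge[[v]] <- c(losses_by_edge[[v]], rownames(matrix$presence)[i])
  }
  ## edge v = edge from parent[v] to v
  edge_nodes <- seq(2L, flat$n)
  lengths <- vapply(edge_nodes, function(v)
    length(gains_by_edge[[v]]) + length(losses_by_edge[[v]]), numeric(1))
  edges <- data.frame(edge = edge_nodes, parent = flat$parent[edge_nodes],
                      length = lengths,
                      tip_label = flat$label[edge_nodes],
                      stringsAsFactors = FALSE)
  assignments <- list()
  for (v in edge_nodes) {
    for (k in gains_by_edge[[v]])
      assignments[[length(assignments) + 1L]] <-
        data.frame(key = k, edge = v, change = "gain", stringsAsFactors = FALSE)
    for (k in losses_by_edge[[v]])
      assignments[[length(assignments) + 1L]] <-
        data.frame(key = k, edge = v, change = "loss", stringsAsFactors = FALSE)
  }
  assignments <- if (length(assignments)) do.call(rbind, assignments) else
    data.frame(key = character(), edge = integer(), change = character())
  stopifnot(sum(edges$length) == total)
  list(score = total, flat = flat, edges = edges, assignments = assignments)
}

## canonical Newick for a lesion topology, with per-edge lengths looked up by
## child node id from a scored flat tree; children ordered by their own
## canonical string
newick_node <- function(node, flat_lookup = NULL) {
  if (is_leaf(node)) return(node$leaf)
  parts <- sort(vapply(node$children, newick_node, character(1)))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Maximum-parsimony tree for one patient
#'
#' Scores every candidate topology and returns the minimum-score tree; among
#' equally parsimonious topologies the one with the lexicographically smallest
#' canonical Newick string is chosen and the tie count is recorded. The trunk
#' edge is the edge joining the root to the lesion subtree.
#'
#' @param cohort An `mpla_cohort`.
#' @param patient_id Patient with >= 2 lesions.
#' @return Object of class `phylo_tree`: `patient_id`, `topology`, `score`,
#'   `n_mpt` (number of equally parsimonious topologies), `edges`,
#'   `assignments`, `trunk_events` (keys on the trunk edge), `newick`.
#' @export
build_parsimony_tree <- function(cohort, patient_id) {
  matrix <- build_event_matrix(cohort, patient_id)
  topologies <- enumerate_topologies(matrix$lesions)
  scored <- lapply(topologies, score_tree, matrix = matrix)
  scores <- vapply(scored, `[[`, numeric(1), "score")
  best <- min(scores)
  tied <- which(scores == best)
  strings <- vapply(topologies[tied], newick_node, character(1))
  pick <- tied[order(strings)[1]]
  chosen <- scored[[pick]]
  ## trunk edge: child node = first node of the lesion subtree (node 3:
  ## root = 1, germline = 2, subtree root = 3)
  trunk_edge <- 3L
  trunk_events <- chosen$assignments$key[chosen$assignments$edge == trunk_edge &
                                           chosen$assignments$change == "gain"]
  ## for a 2-lesion patient node 3 is the subtree root only if >1 lesion node;
  ## flatten always places the lesion subtree at node 3
  tree <- structure(list(patient_id = patient_id, topology = topologies[[pick]],
                         matrix = matrix, score = best,
                         n_mpt = length(tied), edges = chosen$edges,
                         assignments = chosen$assignments,
                         flat = chosen$flat,
                         trunk_events = trunk_events),
                    class = "phylo_tree")
  tree$newick <- to_newick(tree)
  tree
}

#' Newick serialization
#'
#' Writes the germline-rooted tree with branch lengths equal to edge event
#' counts and canonical (lexicographic) child ordering; leaf labels are the
#' lesion ids plus "germline".
#'
#' @param tree A `phylo_tree`.
#' @return A single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree) {
  flat <- tree$flat
  len <- setNames(rep(0, flat$n), seq_len(flat$n))
  len[as.character(tree$edges$edge)] <- tree$edges$length
  render <- function(v) {
    kids <- which(flat$parent == v)
    body <- if (flat$is_tip[v]) flat$label[v] else {
      parts <- sort(vapply(kids, render, character(1)))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    if (v == 1L) body else paste0(body, ":", format(len[[as.character(v)]]))
  }
  paste0(render(1L), ";")
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat("Parsimony tree for", x$patient_id, "- score", x$score,
      "(", x$n_mpt, "equally parsimonious )\n ", x$newick, "\n")
  invisible(x)
}

#' Build trees for every patient of a cohort
#'
#' @param cohort An `mpla_cohort`.
#' @return Named list of `phylo_tree` objects.
#' @export
build_cohort_trees <- function(cohort) {
  ids <- unique(cohort$clinical$patient_id)
  out <- lapply(ids, function(p) build_parsimony_tree(cohort, p))
  names(out) <- ids
  out
}
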