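# Clonal tree construction from per-clone CNV event sets.
#
# Clones are arranged on a rooted tree whose branches carry the CNV
# events acquired on them, under the clonal-evolution assumption that an
# event present in several clones was acquired once in their common
# ancestor. Events are first matched across clones (same chromosome, same
# state, reciprocal gene-index overlap of at least half the shorter
# event), then a greedy perfect-phylogeny grouping repeatedly splits the
# clone set by its most widely shared remaining event.

# Union-find matching of event rows into cross-clone event classes.
match_event_classes <- function(events) {
  ev <- events$events
  n <- nrow(ev)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (ev$chromosome[i] != ev$chromosome[j] || ev$state[i] != ev$state[j]) next
    ov <- min(ev$end_index[i], ev$end_index[j]) -
      max(ev$start_index[i], ev$start_index[j]) + 1
    shorter <- min(ev$n_genes[i], ev$n_genes[j])
    if (ov >= 0.5 * shorter) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  cls <- lapply(split(seq_len(n), comp), function(idx) {
    list(members = idx,
         chromosome = ev$chromosome[idx[1]],
         state = ev$state[idx[1]],
         start_index = min(ev$start_index[idx]),
         end_index = max(ev$end_index[idx]))
  })
  ids <- vapply(cls, function(c)
    sprintf("chr%s:%s:%d-%d", c$chromosome, c$state, c$start_index,
            c$end_index), character(1))
  stats::setNames(cls, make.unique(ids))
}

#' Build a clonal tree from per-clone CNV events
#'
#' The root is the diploid state "normal". At each level the clones are
#' grouped by the event class shared by the largest number of them (ties
#' break by karyotype order then start index); the branch to that group
#' is labeled with every event class common to the whole group, and the
#' grouping recurses on the events that remain. Clones whose events are
#' exhausted attach at the current node. Two clones with disjoint events
#' therefore hang on separate branches directly off the root. Event
#' sharing that is not tree-compatible (overlapping, non-nested carrier
#' sets) is resolved greedily in tie-break order and flagged via
#' `conflict = TRUE`.
#'
#' @param events A `CnvEventSet` from [segment_events()].
#' @return A list of class `CloneTree`: `edges` (data.frame `parent`,
#'   `child` with list column `classes`), `clone_nodes` (clone -> node),
#'   `classes` (event-class metadata), `conflict` (logical).
#' @export
build_clone_tree <- function(events) {
  classes <- match_event_classes(events)
  ev <- events$events
  clone_ids <- sort(unique(ev$clone))
  clone_classes <- lapply(clone_ids, function(cl) {
    rows <- which(ev$clone == cl)
    unique(names(classes)[vapply(rows, function(r)
      which(vapply(classes, function(c) r %in% c$members, logical(1))),
      integer(1))])
  })
  names(clone_classes) <- clone_ids

  edges <- list()
  clone_nodes <- character()
  counter <- 0
  new_node <- function() {
    counter <<- counter + 1
    paste0("n", counter)
  }
  class_order_key <- function(id) {
    c1 <- classes[[id]]
    c(match(c1$chromosome, KARYOTYPE), c1$start_index)
  }

  recurse <- function(node, members, remaining) {
    done <- members[lengths(remaining[members]) == 0]
    for (cl in done) clone_nodes[cl] <<- node
    todo <- setdiff(members, done)
    while (length(todo)) {
      pool <- unique(unlist(remaining[todo], use.names = FALSE))
      counts <- vapply(pool, function(id)
        sum(vapply(todo, function(cl) id %in% remaining[[cl]], logical(1))),
        numeric(1))
      keys <- t(vapply(pool, class_order_key, numeric(2)))
      ord <- order(-counts, keys[, 1], keys[, 2])
      pick <- pool[ord[1]]
      grp <- todo[vapply(todo, function(cl) pick %in% remaining[[cl]],
                         logical(1))]
      shared <- Reduce(intersect, remaining[grp])
      child <- new_node()
      edges[[length(edges) + 1]] <<- list(parent = node, child = child,
                                          classes = shared)
      rem2 <- remaining
      for (cl in grp) rem2[[cl]] <- setdiff(rem2[[cl]], shared)
      recurse(child, grp, rem2)
      todo <- setdiff(todo, grp)
    }
  }
  recurse("normal", clone_ids, clone_classes)

  edge_df <- data.frame(
    parent = vapply(edges, `[[`, character(1), "parent"),
    child = vapply(edges, `[[`, character(1), "child"),
    stringsAsFactors = FALSE)
  edge_df$classes <- lapply(edges, `[[`, "classes")
  used <- unlist(edge_df$classes, use.names = FALSE)
  conflict <- anyDuplicated(used) > 0
  structure(list(edges = edge_df, clone_nodes = clone_nodes,
                 classes = classes, clone_classes = clone_classes,
                 conflict = conflict),
            class = "CloneTree")
}

#' Event classes on a clone's root path
#'
#' @param tree A `CloneTree`.
#' @param clone Clone id.
#' @return Character vector of event-class ids accumulated from the root
#'   down to the clone's node.
#' @export
clone_tree_events <- function(tree, clone) {
  assert_that(clone %in% names(tree$clone_nodes),
              paste("unknown clone:", clone))
  node <- tree$clone_nodes[[clone]]
  acc <- character()
  while (node != "normal") {
    i <- which(tree$edges$child == node)
    acc <- c(tree$edges$classes[[i]], acc)
    node <- tree$edges$parent[i]
  }
  acc
}

#' @export
print.CloneTree <- function(x, ...) {
  cat(sprintf("<CloneTree> %d clones, %d event classes%s\n",
              length(x$clone_nodes), length(x$classes),
              if (x$conflict) " (conflicting sharing resolved greedily)" else ""))
  invisible(x)
}

#' Serialize a clone tree as Newick
#'
#' Leaves are clones; internal branches carry comments listing their event
#' classes. Branch lengths are the number of events acquired on the
#' branch.
#'
#' @param tree A `CloneTree`.
#' @param path Optional output path; when NULL the string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  render <- function(node) {
    kids <- which(tree$edges$parent == node)
    leaves <- names(tree$clone_nodes)[tree$clone_nodes == node]
    parts <- c(
      vapply(leaves, function(cl) paste0(cl, ":0"), character(1)),
      vapply(kids, function(i) {
        cls <- tree$edges$classes[[i]]
        paste0(render(tree$edges$child[i]),
               sprintf("[&&NHX:events=%s]", paste(cls, collapse = "|")),
               ":", length(cls))
      }, character(1)))
    if (length(parts) == 0) return(node)
    paste0("(", paste(parts, collapse = ","), ")", node)
  }
  nwk <- paste0(render("normal"), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Tabulate a clone tree as an edge list
#'
#' @param tree A `CloneTree`.
#' @return data.frame with `parent`, `child`, `n_events`, `events`
#'   (pipe-separated class ids), plus one row per clone attachment.
#' @export
clone_tree_edges <- function(tree) {
  base <- data.frame(
    parent = tree$edges$parent, child = tree$edges$child,
    n_events = lengths(tree$edges$classes),
    events = vapply(tree$edges$classes, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE)
  attach_rows <- data.frame(
    parent = unname(tree$clone_nodes),
    child = names(tree$clone_nodes),
    n_events = 0L, events = "", stringsAsFactors = FALSE)
  rbind(base, attach_rows)
}
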