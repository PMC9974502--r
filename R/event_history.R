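# Event histories: a rooted tree of named nodes, each branch carrying an
# ordered list of karyotype events ("fusion" or "wgd"). Chromosome counts are
# pure arithmetic: fusion -1, whole-genome duplication x2.

#' Create an event history
#'
#' An event history is a rooted tree of named nodes. Each branch (parent ->
#' child) carries an ordered vector of karyotype events, either `"fusion"`
#' (two chromosomes join, count decreases by one) or `"wgd"` (whole-genome
#' duplication, count doubles). Node chromosome counts are derived from the
#' root count by applying branch events in order.
#'
#' @param root Name of the root node.
#' @param root_count Chromosome count at the root (a positive integer; for
#'   diploids this is the number of chromosome pairs).
#' @return An object of class `event_history`.
#' @seealso [add_branch()], [chromosome_count_trajectory()]
#' @examples
#' h <- event_history("chordate_ancestor", 23)
#' h <- add_branch(h, "chordate_ancestor", "pre_1R", rep("fusion", 6))
#' node_counts(h)
#' @export
event_history <- function(root, root_count) {
  root_count <- check_count(root_count, "root_count")
  structure(list(
    nodes = data.frame(node = root, parent = NA_character_,
                       chromosome_count = root_count,
                       stringsAsFactors = FALSE),
    events = stats::setNames(list(), character())
  ), class = "event_history")
}

check_count <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != round(x))
    stop(what, " must be a single positive integer, got: ",
         paste(x, collapse = ","), call. = FALSE)
  as.integer(x)
}

check_events <- function(events) {
  events <- as.character(events)
  bad <- setdiff(unique(events), c("fusion", "wgd"))
  if (length(bad))
    stop("unknown event type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  events
}

#' Apply karyotype events to a chromosome count
#'
#' @param count Starting chromosome count.
#' @param events Character vector of events (`"fusion"`, `"wgd"`), applied in
#'   order.
#' @return The resulting integer count.
#' @examples
#' apply_events(17, c("wgd", rep("fusion", 9), "wgd", rep("fusion", 5))) # 45
#' @export
apply_events <- function(count, events) {
  count <- check_count(count, "count")
  events <- check_events(events)
  for (ev in events) {
    if (ev == "fusion") {
      if (count < 2)
        stop("fusion requires at least two chromosomes (count = ", count, ")",
             call. = FALSE)
      count <- count - 1L
    } else {
      count <- count * 2L
    }
  }
  count
}

#' Add a branch to an event history
#'
#' @param history An [event_history()].
#' @param parent Name of an existing node.
#' @param child Name of the new node.
#' @param events Ordered character vector of events on the branch (may be
#'   empty).
#' @return The extended `event_history`; the child's chromosome count is the
#'   parent's count with `events` applied in order.
#' @export
add_branch <- function(history, parent, child, events = character()) {
  stopifnot(inherits(history, "event_history"))
  if (!parent %in% history$nodes$node)
    stop("unknown parent node: ", parent, call. = FALSE)
  if (child %in% history$nodes$node)
    stop("node already exists: ", child, call. = FALSE)
  events <- check_events(events)
  count <- history$nodes$chromosome_count[history$nodes$node == parent]
  count <- apply_events(count, events)
  history$nodes <- rbind(history$nodes,
                         data.frame(node = child, parent = parent,
                                    chromosome_count = count,
                                    stringsAsFactors = FALSE))
  history$events[[child]] <- events
  history
}

#' Per-node chromosome counts
#'
#' @param history An [event_history()].
#' @return Named integer vector of chromosome counts, one per node.
#' @export
node_counts <- function(history) {
  stopifnot(inherits(history, "event_history"))
  stats::setNames(history$nodes$chromosome_count, history$nodes$node)
}

#' Chromosome-count trajectory along a root-to-node path
#'
#' Walks a path of nodes from the root (or any ancestor) towards a descendant
#' and reports the chromosome count at every node. This is pure arithmetic on
#' the branch events; no simulation is involved.
#'
#' @param history An [event_history()].
#' @param path Character vector of node names forming a parent-to-child walk.
#' @return A data.frame with columns `node` and `count`.
#' @examples
#' h <- vertebrate_event_history()
#' chromosome_count_trajectory(h, c("chordate_ancestor", "pre_1R", "post_1R",
#'   "pre_2R", "post_2R", "jawed_vertebrate", "bird_ancestor"))
#' @export
chromosome_count_trajectory <- function(history, path) {
  stopifnot(inherits(history, "event_history"))
  path <- as.character(path)
  if (!length(path)) stop("path is empty", call. = FALSE)
  unknown <- setdiff(path, history$nodes$node)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(path) > 1L) {
    parents <- history$nodes$parent[match(path[-1L], history$nodes$node)]
    bad <- which(parents != path[-length(path)])
    if (length(bad))
      stop("path is not a parent-to-child walk at: ", path[bad[1L] + 1L],
           call. = FALSE)
  }
  data.frame(node = path,
             count = unname(node_counts(history)[path]),
             stringsAsFactors = FALSE)
}

#' The published chordate-to-bird event history
#'
#' Builds the fixed reference history of vertebrate chromosome evolution: a
#' chordate ancestor with 23 chromosome pairs; three fusions on the branch to
#' Cephalochordata (amphioxus); six fusions on the vertebrate stem giving 17
#' pre-1R chromosomes; the first whole-genome duplication (1R); nine post-1R
#' fusions; the second duplication (2R); five post-2R fusions giving the
#' jawed-vertebrate ancestor 45 pairs; and five fusions on the branch to the
#' bird common ancestor, which had 40 pairs.
#'
#' @param root_count Chromosome count of the chordate ancestor.
#' @param cephalochordate_fusions,stem_fusions,post_1r_fusions,post_2r_fusions,bird_fusions
#'   Number of fusion events on each branch.
#' @return An [event_history()] with nodes `chordate_ancestor`, `amphioxus`,
#'   `pre_1R`, `post_1R`, `pre_2R`, `post_2R`, `jawed_vertebrate`,
#'   `bird_ancestor`.
#' @examples
#' node_counts(vertebrate_event_history())
#' @export
vertebrate_event_history <- function(root_count = 23,
                                     cephalochordate_fusions = 3,
                                     stem_fusions = 6,
                                     post_1r_fusions = 9,
                                     post_2r_fusions = 5,
                                     bird_fusions = 5) {
  h <- event_history("chordate_ancestor", root_count)
  h <- add_branch(h, "chordate_ancestor", "amphioxus",
                  rep("fusion", cephalochordate_fusions))
  h <- add_branch(h, "chordate_ancestor", "pre_1R", rep("fusion", stem_fusions))
  h <- add_branch(h, "pre_1R", "post_1R", "wgd")
  h <- add_branch(h, "post_1R", "pre_2R", rep("fusion", post_1r_fusions))
  h <- add_branch(h, "pre_2R", "post_2R", "wgd")
  h <- add_branch(h, "post_2R", "jawed_vertebrate",
                  rep("fusion", post_2r_fusions))
  h <- add_branch(h, "jawed_vertebrate", "bird_ancestor",
                  rep("fusion", bird_fusions))
  h
}

#' @export
print.event_history <- function(x, ...) {
  cat("Event history with", nrow(x$nodes), "nodes\n")
  for (i in seq_len(nrow(x$nodes))) {
    nd <- x$nodes[i, ]
    ev <- x$events[[nd$node]]
    lab <- if (is.na(nd$parent)) "(root)"
           else sprintf("<- %s [%s]", nd$parent,
                        if (length(ev)) paste(ev, collapse = ",") else "none")
    cat(sprintf("  %-20s %4d  %s\n", nd$node, nd$chromosome_count, lab))
  }
  invisible(x)
}
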