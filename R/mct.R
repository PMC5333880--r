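#' Maximal common transition (MCT) sets
#'
#' Two transitions belong to the same MCT set exactly when they occur in the
#' supports of exactly the same t-invariants, i.e. when their columns in the
#' binary support matrix are identical and nonzero. MCT sets partition the
#' covered transitions into the smallest functional units of the model: a
#' member of an MCT set can never act without the rest of the set. Transitions
#' in no support at all (an uncovered net) are collected separately.
#'
#' @param support binary support matrix (rows = invariants, columns =
#'   transitions)
#' @return object of class `mct_partition`: list with
#'   \describe{
#'     \item{sets}{named list of character vectors (transition ids); canonical
#'       order: decreasing size, ties broken lexicographically by member
#'       order; non-trivial sets are named `m1`, `m2`, ..., trivial
#'       (single-transition) sets carry their transition's id}
#'     \item{trivial}{logical vector, per set: size 1}
#'     \item{connected}{placeholder (NA) until [mct_subnet_connected()] is
#'       applied with a net}
#'     \item{uncovered}{character vector of all-zero columns}
#'   }
#' @examples
#' S <- rbind(c(1, 1, 0), c(1, 1, 1))
#' colnames(S) <- c("t1", "t2", "t3")
#' compute_mct_sets(S)
#' @export
compute_mct_sets <- function(support) {
  support <- as.matrix(support) != 0
  tl <- colnames(support)
  if (is.null(tl)) tl <- paste0("t", seq_len(ncol(support)))

  pattern <- apply(support, 2, function(col) paste(as.integer(col), collapse = ""))
  covered <- colSums(support) > 0
  uncovered <- tl[!covered]

  groups <- split(tl[covered], pattern[covered])
  # canonical order: by size descending, then by first member's column position
  first_pos <- vapply(groups, function(g) min(match(g, tl)), numeric(1))
  ord <- order(-lengths(groups), first_pos)
  groups <- unname(groups[ord])
  trivial <- lengths(groups) == 1L

  nm <- character(length(groups))
  nm[!trivial] <- paste0("m", seq_len(sum(!trivial)))
  nm[trivial] <- vapply(groups[trivial], `[[`, character(1), 1L)
  names(groups) <- nm

  structure(list(sets = groups, trivial = trivial,
                 connected = rep(NA, length(groups)), uncovered = uncovered),
            class = "mct_partition")
}

#' @export
print.mct_partition <- function(x, ...) {
  nt <- sum(!x$trivial)
  cat(sprintf("<mct_partition> %d sets (%d non-trivial), %d uncovered transitions\n",
              length(x$sets), nt, length(x$uncovered)))
  for (i in which(!x$trivial))
    cat(sprintf("  %-4s {%s}\n", names(x$sets)[i], paste(x$sets[[i]], collapse = ", ")))
  invisible(x)
}

#' Connectivity of the subnet induced by a transition set
#'
#' An MCT set can induce a disconnected subnet: a pair of its transitions may
#' only be linked through transitions outside the set. The induced subnet here
#' is the given transitions plus all their adjacent places and the arcs among
#' them; connectivity is judged on the undirected sense. A singleton set is
#' connected by convention. Places shared between two different MCT sets do
#' not merge the sets — each set's subnet is built independently.
#'
#' @param net a `petri_net`
#' @param transitions character vector of transition ids (subset of the net's)
#' @return logical scalar
#' @export
mct_subnet_connected <- function(net, transitions) {
  stopifnot(inherits(net, "petri_net"))
  unknown <- setdiff(transitions, transition_ids(net))
  if (length(unknown)) stop("unknown transitions: ", paste(unknown, collapse = ", "))
  if (length(transitions) <= 1L) return(TRUE)
  a <- net$arcs
  touch <- a$source %in% transitions | a$target %in% transitions
  sub <- a[touch, , drop = FALSE]
  verts <- unique(c(transitions, sub$source, sub$target))
  g <- igraph::graph_from_data_frame(sub[, c("source", "target")],
                                     directed = FALSE, vertices = verts)
  comp <- igraph::components(g)$membership
  length(unique(comp[transitions])) == 1L
}

#' Annotate an MCT partition with induced-subnet connectivity
#'
#' @param mct an `mct_partition`
#' @param net the `petri_net` the support matrix came from
#' @return the partition with its `connected` flags filled in
#' @export
mct_connectivity <- function(mct, net) {
  stopifnot(inherits(mct, "mct_partition"))
  mct$connected <- vapply(mct$sets, function(s) mct_subnet_connected(net, s), logical(1))
  mct
}
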