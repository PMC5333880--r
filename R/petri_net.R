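#' Construct a Petri net
#'
#' A Petri net is the 5-tuple (P, T, F, W, M0): a finite set of places, a
#' finite set of transitions, a set of directed arcs connecting places to
#' transitions and vice versa, positive integer arc weights, and an initial
#' marking assigning a non-negative token count to every place. Places model
#' the passive components of a system (compounds, states), transitions the
#' active ones (elementary processes), and the token flow the system dynamics.
#'
#' @param places character vector of place ids, or a data frame with columns
#'   `id` and `name`. When only ids are given, names default to the ids.
#' @param transitions character vector of transition ids, or a data frame with
#'   columns `id` and `name`.
#' @param arcs data frame with columns `source`, `target` and optionally
#'   `weight` (default 1). Every arc must connect a place to a transition or a
#'   transition to a place; at most one arc per ordered (source, target) pair.
#' @param marking named non-negative integer vector of initial token counts;
#'   places not named get 0 tokens. `NULL` means the empty marking.
#'
#' @return An object of class `petri_net`: a list with elements `places`,
#'   `transitions` (data frames with `id`, `name`), `arcs` (data frame with
#'   `source`, `target`, `weight`) and `marking` (named integer vector in
#'   place order).
#'
#' @examples
#' net <- petri_net(c("p1", "p2"), c("t1"),
#'                  data.frame(source = c("p1", "t1"), target = c("t1", "p2")),
#'                  marking = c(p1 = 1))
#' incidence_matrix(net)
#' @export
petri_net <- function(places, transitions, arcs = NULL, marking = NULL) {
  places <- as_node_table(places, "place")
  transitions <- as_node_table(transitions, "transition")

  if (anyDuplicated(places$id))
    stop("duplicate place ids: ", paste(unique(places$id[duplicated(places$id)]), collapse = ", "))
  if (anyDuplicated(transitions$id))
    stop("duplicate transition ids: ", paste(unique(transitions$id[duplicated(transitions$id)]), collapse = ", "))
  clash <- intersect(places$id, transitions$id)
  if (length(clash))
    stop("place and transition ids must be disjoint; shared: ", paste(clash, collapse = ", "))
  if (nrow(places) + nrow(transitions) == 0L)
    stop("a Petri net needs at least one place or transition")

  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- data.frame(source = character(), target = character(),
                       weight = integer(), stringsAsFactors = FALSE)
  } else {
    arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(arcs)))
      stop("`arcs` needs columns `source` and `target`")
    if (is.null(arcs$weight)) arcs$weight <- 1L
    arcs <- arcs[, c("source", "target", "weight")]
    arcs$source <- as.character(arcs$source)
    arcs$target <- as.character(arcs$target)
    if (any(is.na(arcs$weight)) || any(arcs$weight < 1) || any(arcs$weight != round(arcs$weight)))
      stop("arc weights must be positive integers")
    arcs$weight <- as.integer(arcs$weight)

    key <- paste(arcs$source, arcs$target, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate arc declaration: ",
           paste(unique(sub("\r", " -> ", key[duplicated(key)])), collapse = ", "))

    is_p_src <- arcs$source %in% places$id
    is_t_src <- arcs$source %in% transitions$id
    is_p_dst <- arcs$target %in% places$id
    is_t_dst <- arcs$target %in% transitions$id
    unknown <- !(is_p_src | is_t_src) | !(is_p_dst | is_t_dst)
    if (any(unknown))
      stop("arc references unknown node: ",
           paste(arcs$source[unknown][1], "->", arcs$target[unknown][1]))
    bad <- !((is_p_src & is_t_dst) | (is_t_src & is_p_dst))
    if (any(bad))
      stop("arc does not connect a place and a transition (net must be bipartite): ",
           paste(arcs$source[bad][1], "->", arcs$target[bad][1]))
    rownames(arcs) <- NULL
  }

  m0 <- stats::setNames(integer(nrow(places)), places$id)
  if (!is.null(marking) && length(marking)) {
    if (is.null(names(marking)))
      stop("`marking` must be a named vector (place id -> tokens)")
    unknown <- setdiff(names(marking), places$id)
    if (length(unknown))
      stop("marking references unknown places: ", paste(unknown, collapse = ", "))
    if (any(marking < 0) || any(marking != round(marking)))
      stop("token counts must be non-negative integers")
    m0[names(marking)] <- as.integer(marking)
  }

  structure(list(places = places, transitions = transitions,
                 arcs = arcs, marking = m0),
            class = "petri_net")
}

as_node_table <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"id" %in% names(x)) stop("`", what, "s` data frame needs an `id` column")
    out <- data.frame(id = as.character(x$id),
                      name = if (is.null(x$name)) as.character(x$id) else as.character(x$name),
                      stringsAsFactors = FALSE)
  } else {
    x <- as.character(x)
    out <- data.frame(id = x, name = x, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.petri_net <- function(x, ...) {
  cat(sprintf("<petri_net> %d places, %d transitions, %d arcs, %d tokens\n",
              nrow(x$places), nrow(x$transitions), nrow(x$arcs), sum(x$marking)))
  invisible(x)
}

#' @rdname petri_net
#' @param net a `petri_net`
#' @export
place_ids <- function(net) net$places$id

#' @rdname petri_net
#' @export
transition_ids <- function(net) net$transitions$id

#' Coerce a token vector to a marking of a net
#'
#' @param net a `petri_net`
#' @param x named vector (place id -> tokens), unnamed vector in place order,
#'   or `NULL` for the net's initial marking.
#' @return named integer vector over all places, in place order
#' @export
as_marking <- function(net, x = NULL) {
  if (is.null(x)) return(net$marking)
  p <- place_ids(net)
  if (is.null(names(x))) {
    if (length(x) != length(p))
      stop("marking length ", length(x), " != number of places ", length(p))
    x <- stats::setNames(x, p)
  }
  m <- stats::setNames(integer(length(p)), p)
  unknown <- setdiff(names(x), p)
  if (length(unknown)) stop("marking references unknown places: ", paste(unknown, collapse = ", "))
  m[names(x)] <- as.integer(x)
  if (any(m < 0)) stop("negative token count in marking")
  m
}

#' Incidence matrix of a Petri net
#'
#' The n x m integer matrix A with rows indexed by places and columns by
#' transitions; entry a_ij is the net token change of place p_i when
#' transition t_j fires, i.e. W(t_j -> p_i) - W(p_i -> t_j) (0 when neither
#' arc exists). For any marking M at which t_j is enabled, firing t_j yields
#' M' with M' - M equal to column j.
#'
#' @param net a `petri_net`
#' @return integer matrix with `dimnames` = (place ids, transition ids)
#' @export
incidence_matrix <- function(net) {
  p <- place_ids(net); tt <- transition_ids(net)
  A <- matrix(0L, nrow = length(p), ncol = length(tt), dimnames = list(p, tt))
  a <- net$arcs
  if (nrow(a)) {
    pt <- a$source %in% p            # place -> transition: consumption
    if (any(pt))
      A[cbind(match(a$source[pt], p), match(a$target[pt], tt))] <-
        A[cbind(match(a$source[pt], p), match(a$target[pt], tt))] - a$weight[pt]
    tp <- !pt                        # transition -> place: production
    if (any(tp))
      A[cbind(match(a$target[tp], p), match(a$source[tp], tt))] <-
        A[cbind(match(a$target[tp], p), match(a$source[tp], tt))] + a$weight[tp]
  }
  A
}

# consumption (place->transition weights) and production (transition->place)
# matrices, both n x m; A = production - consumption
flow_matrices <- function(net) {
  p <- place_ids(net); tt <- transition_ids(net)
  con <- matrix(0L, length(p), length(tt), dimnames = list(p, tt))
  pro <- con
  a <- net$arcs
  if (nrow(a)) {
    pt <- a$source %in% p
    con[cbind(match(a$source[pt], p), match(a$target[pt], tt))] <- a$weight[pt]
    pro[cbind(match(a$target[!pt], p), match(a$source[!pt], tt))] <- a$weight[!pt]
  }
  list(consumption = con, production = pro)
}

#' Transitions enabled at a marking
#'
#' A transition is enabled when every one of its pre-places holds at least as
#' many tokens as the weight of the connecting arc. A transition with no
#' pre-places is enabled at every marking.
#'
#' @param net a `petri_net`
#' @param marking marking (see [as_marking()]); default the initial marking
#' @return character vector of enabled transition ids (in transition order)
#' @export
enabled_transitions <- function(net, marking = NULL) {
  m <- as_marking(net, marking)
  con <- flow_matrices(net)$consumption
  ok <- colSums(con > m) == 0L       # every pre-place satisfies its weight
  transition_ids(net)[ok]
}

#' Fire a transition
#'
#' Removes `W(p -> t)` tokens from each pre-place and adds `W(t -> p)` tokens
#' to each post-place. Value-semantic: the input marking is not modified.
#'
#' @param net a `petri_net`
#' @param marking marking at which to fire (see [as_marking()])
#' @param t transition id
#' @return the successor marking (named integer vector)
#' @export
fire_transition <- function(net, marking, t) {
  m <- as_marking(net, marking)
  if (!t %in% transition_ids(net)) stop("unknown transition: ", t)
  fl <- flow_matrices(net)
  if (any(fl$consumption[, t] > m))
    stop("transition ", t, " is not enabled at this marking")
  m + fl$production[, t] - fl$consumption[, t]
}

#' Structural property report
#'
#' Checks the standard structural properties of a place/transition net:
#' \describe{
#'   \item{ordinary}{all arc weights equal 1}
#'   \item{homogeneous}{for every place, all outgoing arcs carry one weight}
#'   \item{pure}{no pair of oppositely directed arcs between the same place
#'     and transition (no read arcs)}
#'   \item{connected}{the underlying undirected graph is connected (isolated
#'     vertices make the net disconnected)}
#'   \item{strongly_connected}{the directed graph is strongly connected}
#'   \item{structurally_conflict_free}{no place has two or more outgoing arcs}
#' }
#'
#' @param net a `petri_net`
#' @return a list of six logicals with class `structural_report`
#' @export
structural_report <- function(net) {
  a <- net$arcs
  p <- place_ids(net)

  ordinary <- all(a$weight == 1L)
  out_of_place <- a[a$source %in% p, , drop = FALSE]
  homogeneous <- all(tapply(out_of_place$weight, out_of_place$source,
                            function(w) length(unique(w)) == 1L), na.rm = TRUE)
  if (!nrow(out_of_place)) homogeneous <- TRUE
  pure <- !any(paste(a$source, a$target) %in% paste(a$target, a$source))
  scf <- !any(table(out_of_place$source) >= 2L)

  ids <- c(p, transition_ids(net))
  g <- igraph::graph_from_data_frame(a[, c("source", "target")],
                                     directed = TRUE, vertices = ids)
  connected <- length(ids) <= 1L || igraph::is_connected(g, mode = "weak")
  strongly <- length(ids) <= 1L || igraph::is_connected(g, mode = "strong")

  structure(list(ordinary = ordinary, homogeneous = homogeneous, pure = pure,
                 connected = connected, strongly_connected = strongly,
                 structurally_conflict_free = scf),
            class = "structural_report")
}

#' @export
print.structural_report <- function(x, ...) {
  cat("Structural properties:\n")
  for (nm in names(x)) cat(sprintf("  %-27s %s\n", nm, x[[nm]]))
  invisible(x)
}
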