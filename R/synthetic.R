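#' Generate a random covered Petri net
#'
#' Builds a net as a union of `n_circuits` randomly drawn directed circuits
#' (alternating place/transition cycles) that share places, so the result is
#' by construction ordinary (all weights 1), pure (no read arcs), connected,
#' and covered by t-invariants: each circuit's transition set, fired once
#' each, reproduces any marking. Every transition belongs to exactly one
#' circuit; places may be shared between circuits.
#'
#' The parameters must admit such a net: each circuit needs at least 2
#' transitions (a 1-transition "circuit" would be a read arc) and at most
#' `n_places` distinct places, every place must appear in some circuit, and
#' every circuit after the first must share a place with an earlier one.
#'
#' @param n_places number of places (>= 2)
#' @param n_transitions number of transitions (>= 2 * n_circuits)
#' @param n_circuits number of circuits (>= 1)
#' @param seed integer seed; the same seed always yields the identical net
#' @param tokens one of `"circuit"` (one token on a random place of each
#'   circuit, so every circuit can run) or `"empty"`
#' @return a `petri_net` with places `p1..`, transitions `t1..`
#' @export
generate_covered_net <- function(n_places, n_transitions, n_circuits = 1,
                                 seed = 1, tokens = c("circuit", "empty")) {
  tokens <- match.arg(tokens)
  if (n_circuits < 1 || n_places < 2 || n_transitions < 2 * n_circuits)
    stop("infeasible parameters: need n_circuits >= 1, n_places >= 2 and ",
         "n_transitions >= 2 * n_circuits")
  if (n_transitions - (n_circuits - 1) < n_places)
    stop("infeasible parameters: not enough transition slots to use every ",
         "place (need n_transitions - n_circuits + 1 >= n_places)")
  set.seed(seed)

  pls <- paste0("p", seq_len(n_places))
  trs <- paste0("t", seq_len(n_transitions))

  # random composition of n_transitions into n_circuits parts, each >= 2
  # and <= n_places (distinct places within one circuit)
  sizes <- rep(2L, n_circuits)
  spare <- n_transitions - sum(sizes)
  while (spare > 0) {
    i <- sample(which(sizes < n_places), 1)
    sizes[i] <- sizes[i] + 1L
    spare <- spare - 1L
  }
  if (any(sizes > n_places))
    stop("infeasible parameters: a circuit needs more distinct places than exist")

  tgroups <- split(sample(trs), rep(seq_len(n_circuits), times = sizes))
  unused <- sample(pls)
  used <- character()
  arcs <- vector("list", n_circuits)
  seeds_tok <- character(n_circuits)

  for (i in seq_len(n_circuits)) {
    k <- sizes[i]
    sel <- character()
    if (i > 1) sel <- sample(used, 1)                     # join earlier circuits
    take <- min(k - length(sel), length(unused))
    if (take > 0) { sel <- c(sel, unused[seq_len(take)]); unused <- unused[-seq_len(take)] }
    if (length(sel) < k)
      sel <- c(sel, sample(setdiff(used, sel), k - length(sel)))
    sel <- sample(sel)                                    # random circuit order
    used <- union(used, sel)
    ts <- tgroups[[i]]
    arcs[[i]] <- data.frame(
      source = c(sel, ts),
      target = c(ts, sel[c(seq_len(k)[-1], 1L)]),
      weight = 1L, stringsAsFactors = FALSE)
    seeds_tok[i] <- sel[1]
  }

  marking <- NULL
  if (tokens == "circuit") {
    marking <- table(seeds_tok)
    marking <- stats::setNames(as.integer(marking), names(marking))
  }
  petri_net(pls, trs, do.call(rbind, arcs), marking)
}

#' Generate a binary support matrix with planted MCT blocks
#'
#' Emulates the block structure of a real invariant support matrix: each
#' block plants a set of transition columns with identical invariant
#' membership (a planted MCT set). Optional per-cell flip noise degrades the
#' blocks. The planted partition is returned so recovery can be checked.
#'
#' @param n_invariants number of rows
#' @param block_spec list of blocks, each a list with `size` (number of
#'   transition columns) and `invariants` (integer vector of row indices in
#'   which the block occurs, non-empty). Two blocks with identical invariant
#'   subsets would merge into one MCT set and are rejected.
#' @param noise probability of flipping each cell (default 0)
#' @param seed integer seed
#' @return list with `support` (binary matrix, rows `x1..`, columns `t1..`)
#'   and `blocks` (named list of planted column-id sets, `m1`, `m2`, ...)
#' @export
generate_block_support_matrix <- function(n_invariants, block_spec,
                                          noise = 0, seed = 1) {
  stopifnot(n_invariants >= 1, length(block_spec) >= 1, noise >= 0, noise < 1)
  subsets <- lapply(block_spec, function(b) sort(unique(as.integer(b$invariants))))
  if (any(lengths(subsets) == 0))
    stop("every block needs a non-empty invariant subset")
  if (any(vapply(subsets, function(s) any(s < 1 | s > n_invariants), logical(1))))
    stop("block invariant subset out of range")
  keys <- vapply(subsets, paste, character(1), collapse = ",")
  if (anyDuplicated(keys))
    stop("blocks with identical invariant subsets overlap into one MCT set")
  set.seed(seed)
  sizes <- vapply(block_spec, function(b) as.integer(b$size), integer(1))
  stopifnot(all(sizes >= 1))
  m <- sum(sizes)
  S <- matrix(0L, n_invariants, m,
              dimnames = list(paste0("x", seq_len(n_invariants)),
                              paste0("t", seq_len(m))))
  col0 <- cumsum(c(0L, sizes))
  blocks <- list()
  for (b in seq_along(block_spec)) {
    cols <- (col0[b] + 1L):col0[b + 1L]
    S[subsets[[b]], cols] <- 1L
    blocks[[paste0("m", b)]] <- colnames(S)[cols]
  }
  if (noise > 0) {
    flip <- matrix(stats::runif(length(S)) < noise, nrow(S))
    S[flip] <- 1L - S[flip]
  }
  list(support = S, blocks = blocks)
}
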