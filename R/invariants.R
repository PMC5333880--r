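#' Minimal t-invariants of a Petri net
#'
#' A t-invariant is a non-negative integer vector x with A.x = 0: firing each
#' transition t_j exactly x_j times reproduces the marking, so its support
#' supp(x) = {t_j : x_j > 0} describes a self-contained subprocess. The
#' minimal invariants are those whose supports contain no other invariant's
#' support; every invariant is a non-negative combination of minimal ones.
#'
#' The computation uses the classical Fourier-Motzkin/Farkas tableau
#' \code{[A' | I]}: place rows are eliminated one at a time by taking all
#' non-negative combinations of opposite-sign row pairs, pruning rows whose
#' support strictly contains another row's support after every elimination
#' step, and gcd-normalizing. All arithmetic is exact integer arithmetic and
#' every returned vector is re-verified against A before return.
#'
#' @param A incidence matrix (places x transitions) as produced by
#'   [incidence_matrix()], or a `petri_net` (its incidence matrix is used).
#' @param limit maximum number of intermediate tableau rows; exceeding it
#'   raises an error of class `petrinv_limit_error` carrying the count reached
#'   (never silent truncation).
#' @return integer matrix with one row per minimal invariant (rownames
#'   `x1`, `x2`, ...; colnames = transition ids), in canonical order: by
#'   support size, then lexicographically by support. Zero rows mean there are
#'   no invariants and the matrix has 0 rows.
#' @examples
#' net <- petri_net(c("p1", "p2"), c("t1", "t2"),
#'                  data.frame(source = c("p1", "t1", "p2", "t2"),
#'                             target = c("t1", "p2", "t2", "p1")))
#' minimal_t_invariants(net)
#' @export
minimal_t_invariants <- function(A, limit = 1e5) {
  if (inherits(A, "petri_net")) A <- incidence_matrix(A)
  A <- as.matrix(A)
  if (any(A != round(A))) stop("incidence matrix must be integer")
  inv <- farkas_minimal_semiflows(A, limit = limit)
  colnames(inv) <- colnames(A)
  if (nrow(inv)) rownames(inv) <- paste0("x", seq_len(nrow(inv)))
  inv
}

#' Minimal p-invariants of a Petri net
#'
#' A p-invariant is a non-negative integer vector y with A'.y = 0; the
#' y-weighted token sum over its support places is constant under any firing,
#' i.e. a conservation law. Computed as the minimal t-invariants of the
#' transposed incidence matrix.
#'
#' @inheritParams minimal_t_invariants
#' @return integer matrix, one row per minimal p-invariant (rownames `y1`,
#'   ...; colnames = place ids)
#' @export
minimal_p_invariants <- function(A, limit = 1e5) {
  if (inherits(A, "petri_net")) A <- incidence_matrix(A)
  A <- as.matrix(A)
  inv <- farkas_minimal_semiflows(t(A), limit = limit)
  colnames(inv) <- rownames(A)
  if (nrow(inv)) rownames(inv) <- paste0("y", seq_len(nrow(inv)))
  inv
}

# Minimal non-negative integer solutions of M %*% x = 0 (support-minimal,
# gcd-reduced). M is r x m; returns a k x m integer matrix.
farkas_minimal_semiflows <- function(M, limit = 1e5) {
  r <- nrow(M); m <- ncol(M)
  tab <- cbind(t(M), diag(1, m))            # m rows, r + m columns
  storage.mode(tab) <- "double"             # exact for |entries| < 2^53

  for (j in seq_len(r)) {
    col <- tab[, j]
    zero <- tab[col == 0, , drop = FALSE]
    pos <- which(col > 0); neg <- which(col < 0)
    if (length(pos) && length(neg)) {
      grid <- expand.grid(ip = pos, ineg = neg)
      new <- matrix(0, nrow(grid), ncol(tab))
      for (k in seq_len(nrow(grid))) {
        ip <- grid$ip[k]; ineg <- grid$ineg[k]
        v <- abs(col[ineg]) * tab[ip, ] + col[ip] * tab[ineg, ]
        g <- vec_gcd(v)
        if (g > 1) v <- v / g
        new[k, ] <- v
      }
      tab <- rbind(zero, new)
    } else {
      tab <- zero
    }
    if (nrow(tab) > 1) tab <- prune_nonminimal(tab, r)
    if (nrow(tab) > limit) {
      cond <- structure(class = c("petrinv_limit_error", "error", "condition"),
                        list(message = sprintf(
                               "invariant tableau exceeded limit (%d rows reached, limit %d)",
                               nrow(tab), as.integer(limit)),
                             call = sys.call(-1), rows = nrow(tab)))
      stop(cond)
    }
    if (nrow(tab) && max(abs(tab)) >= 2^52)
      stop("tableau entries too large for exact double arithmetic")
  }

  inv <- tab[, r + seq_len(m), drop = FALSE]
  inv <- inv[rowSums(inv) > 0, , drop = FALSE]
  if (nrow(inv)) {
    g <- apply(inv, 1, vec_gcd)
    inv <- inv / g
    inv <- inv[!duplicated(inv), , drop = FALSE]
    # final support-minimality filter and soundness assertion
    supp <- inv > 0
    keep <- vapply(seq_len(nrow(inv)), function(i) {
      !any(vapply(seq_len(nrow(inv)), function(k) {
        k != i && all(supp[k, ] <= supp[i, ]) && any(supp[k, ] < supp[i, ])
      }, logical(1)))
    }, logical(1))
    inv <- inv[keep, , drop = FALSE]
    if (nrow(inv) && any(M %*% t(inv) != 0))
      stop("internal error: candidate invariant fails its defining equation")
    inv <- inv[canonical_invariant_order(inv > 0), , drop = FALSE]
  }
  storage.mode(inv) <- "integer"
  inv
}

# drop rows whose support (identity block, columns > r_offset used entirely:
# support over the full identity part) strictly contains another row's support
prune_nonminimal <- function(tab, r) {
  supp <- tab[, (r + 1):ncol(tab), drop = FALSE] > 0
  n <- nrow(tab)
  # cheap dedupe first
  dup <- duplicated(tab)
  tab <- tab[!dup, , drop = FALSE]; supp <- supp[!dup, , drop = FALSE]
  n <- nrow(tab)
  if (n <= 1) return(tab)
  sizes <- rowSums(supp)
  ord <- order(sizes)
  supp <- supp[ord, , drop = FALSE]; tab <- tab[ord, , drop = FALSE]
  sizes <- sizes[ord]
  keep <- rep(TRUE, n)
  S <- supp * 1
  for (i in seq_len(n)) {
    if (!keep[i]) next
    # rows whose support is a superset of row i's support (larger size only)
    cand <- which(keep & sizes > sizes[i])
    if (!length(cand)) next
    hit <- (S[cand, , drop = FALSE] %*% S[i, ]) == sizes[i]
    keep[cand[hit]] <- FALSE
  }
  tab[keep, , drop = FALSE]
}

canonical_invariant_order <- function(supp) {
  key <- apply(supp, 1, function(s) paste(sprintf("%06d", which(s)), collapse = ","))
  order(rowSums(supp), key)
}

vec_gcd <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  Reduce(gcd2, v)
}

gcd2 <- function(a, b) {
  while (b != 0) { tmp <- a %% b; a <- b; b <- tmp }
  a
}

#' Binary support matrix of a set of t-invariants
#'
#' @param invariants invariant coefficient matrix as returned by
#'   [minimal_t_invariants()] (rows = invariants, columns = transitions)
#' @param transitions optional character vector giving the full transition
#'   label set/order; defaults to the matrix colnames
#' @return binary (0/1) integer matrix, rows = invariants, columns =
#'   transitions; entry 1 iff the transition is in the invariant's support
#' @export
build_support_matrix <- function(invariants, transitions = NULL) {
  inv <- as.matrix(invariants)
  if (is.null(transitions)) transitions <- colnames(inv)
  if (is.null(transitions)) transitions <- paste0("t", seq_len(ncol(inv)))
  if (!is.null(colnames(inv)) && !setequal(colnames(inv), transitions))
    stop("invariant columns do not match the requested transition set")
  S <- matrix(0L, nrow(inv), length(transitions),
              dimnames = list(rownames(inv), transitions))
  if (!is.null(colnames(inv))) {
    S[, colnames(inv)] <- (inv > 0) * 1L
  } else {
    S[] <- (inv > 0) * 1L
  }
  S
}

#' Net coverage by t-invariants
#'
#' A net is covered by t-invariants when every transition belongs to at least
#' one invariant support; only then does every modeled elementary process
#' contribute to some stationary subprocess.
#'
#' @param support binary support matrix (rows = invariants, columns =
#'   transitions)
#' @return list with `covered` (logical) and `uncovered` (character vector of
#'   transition labels in no support)
#' @export
check_coverage <- function(support) {
  support <- as.matrix(support)
  hit <- colSums(support != 0) > 0
  labels <- colnames(support)
  if (is.null(labels)) labels <- paste0("t", seq_along(hit))
  list(covered = all(hit), uncovered = labels[!hit])
}

#' Feasibility preconditions for t-invariants
#'
#' Minimal t-invariants may be unrealizable from the initial marking for two
#' structural reasons: read arcs (oppositely directed arc pairs, absent in a
#' pure net) and minimal p-invariants whose support holds too few tokens
#' initially. When the net is pure and has no p-invariants, all t-invariants
#' may be treated as feasible; this function reports exactly those
#' preconditions without any reachability analysis.
#'
#' @param net a `petri_net`
#' @param p_invariants optional precomputed matrix from
#'   [minimal_p_invariants()]; computed from the net when missing
#' @return list with `has_read_arcs`, `empty_p_invariant_set`, `all_feasible`
#'   (both preconditions favorable) and `p_invariant_token_sums` (initial
#'   weighted token sum for each minimal p-invariant)
#' @export
feasibility_preconditions <- function(net, p_invariants = NULL) {
  stopifnot(inherits(net, "petri_net"))
  if (is.null(p_invariants)) p_invariants <- minimal_p_invariants(net)
  has_read_arcs <- !structural_report(net)$pure
  sums <- if (nrow(p_invariants)) as.numeric(p_invariants %*% net$marking[colnames(p_invariants)]) else numeric()
  names(sums) <- rownames(p_invariants)
  list(has_read_arcs = has_read_arcs,
       empty_p_invariant_set = nrow(p_invariants) == 0L,
       all_feasible = !has_read_arcs && nrow(p_invariants) == 0L,
       p_invariant_token_sums = sums)
}
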