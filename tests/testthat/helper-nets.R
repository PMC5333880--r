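# Shared toy nets and independent oracles.

# p1 -> t1 -> p2: the smallest useful chain
chain_net <- function(tokens = 1L) {
  petri_net(c("p1", "p2"), "t1",
            data.frame(source = c("p1", "t1"), target = c("t1", "p2")),
            marking = c(p1 = tokens))
}

# closed circuit p1 -> t1 -> p2 -> t2 -> p1
cycle_net <- function(tokens = 1L) {
  petri_net(c("p1", "p2"), c("t1", "t2"),
            data.frame(source = c("p1", "t1", "p2", "t2"),
                       target = c("t1", "p2", "t2", "p1")),
            marking = c(p1 = tokens))
}

# small random net that need not be covered or connected: random bipartite
# arcs with weights in 1..wmax, deduplicated
random_net <- function(n, m, n_arcs, wmax = 2, seed = 1) {
  set.seed(seed)
  pls <- paste0("p", seq_len(n)); trs <- paste0("t", seq_len(m))
  src_p <- sample(c(TRUE, FALSE), n_arcs, replace = TRUE)
  arcs <- data.frame(
    source = ifelse(src_p, sample(pls, n_arcs, TRUE), sample(trs, n_arcs, TRUE)),
    target = ifelse(src_p, sample(trs, n_arcs, TRUE), sample(pls, n_arcs, TRUE)),
    weight = sample(wmax, n_arcs, TRUE), stringsAsFactors = FALSE)
  arcs <- arcs[!duplicated(arcs[, c("source", "target")]), ]
  marking <- stats::setNames(sample(0:2, n, TRUE), pls)
  petri_net(pls, trs, arcs, marking[marking > 0])
}

# direct-definition oracle for enabledness: loop over every (pre-place, weight)
oracle_enabled <- function(net, marking) {
  m <- as_marking(net, marking)
  vapply(transition_ids(net), function(t) {
    pre <- net$arcs[net$arcs$target == t, , drop = FALSE]
    all(m[pre$source] >= pre$weight)
  }, logical(1))
}

# bounded exhaustive oracle for minimal t-invariants: enumerate every
# non-negative integer vector with entries <= B, keep exact solutions of
# A x = 0, reduce by gcd, dedupe, filter to support-minimal supports
oracle_minimal_invariants <- function(A, B = 6) {
  m <- ncol(A)
  grid <- as.matrix(expand.grid(rep(list(0:B), m)))
  sol <- grid[rowSums(abs(grid %*% t(A))) == 0 & rowSums(grid) > 0, , drop = FALSE]
  if (!nrow(sol)) return(matrix(0L, 0, m))
  g <- apply(sol, 1, function(v) Reduce(function(a, b) if (b) Recall(b, a %% b) else a, v[v > 0]))
  sol <- unique(sol / g)
  supp <- sol > 0
  keep <- vapply(seq_len(nrow(sol)), function(i)
    !any(vapply(seq_len(nrow(sol)), function(k)
      k != i && all(supp[k, ] <= supp[i, ]) && any(supp[k, ] < supp[i, ]),
      logical(1))), logical(1))
  out <- sol[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- colnames(A)
  out
}

# invariant sets as comparable canonical strings (rows order-free)
invariant_set_key <- function(M) {
  if (!nrow(M)) return(character())
  sort(unname(apply(M, 1, paste, collapse = ",")))
}

# O(m^2) pairwise-comparison oracle for MCT classes
oracle_mct <- function(S) {
  S <- as.matrix(S) != 0
  tl <- colnames(S)
  covered <- which(colSums(S) > 0)
  classes <- list()
  assigned <- rep(FALSE, ncol(S))
  for (j in covered) {
    if (assigned[j]) next
    cls <- j
    for (k in covered) {
      if (k != j && !assigned[k] && all(S[, j] == S[, k])) cls <- c(cls, k)
    }
    assigned[cls] <- TRUE
    classes[[length(classes) + 1L]] <- sort(tl[cls])
  }
  classes
}

# literal formula oracles for the row distances
oracle_dist <- function(x, y, metric, p = 2) {
  switch(metric,
    binary = {
      nz <- x != 0 | y != 0
      if (!any(nz)) 0 else sum((x != 0) != (y != 0) & nz) / sum(nz)
    },
    canberra = {
      keep <- !(x == 0 & y == 0)
      sum(abs(x[keep] - y[keep]) / (abs(x[keep]) + abs(y[keep])))
    },
    correlation = 1 - sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
    uncentered = 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    maximum = max(abs(x - y)),
    minkowski = sum(abs(x - y)^p)^(1 / p))
}

# definition-level agglomeration oracle for single/complete linkage:
# at each step recompute every cluster pair's distance from the original
# matrix (min for single, max for complete) instead of Lance-Williams updates
oracle_linkage <- function(D, method = c("single", "complete")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  f <- if (method == "single") min else max
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  partitions <- list(lapply(clusters, identity))
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- f(D[clusters[[i]], clusters[[j]]])
      if (dd < bd) { bd <- dd; best <- c(j, i) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bd)
    partitions <- c(partitions, list(clusters))
  }
  list(heights = heights, partitions = partitions)
}

# literal silhouette formula oracle
oracle_silhouette <- function(cl, D) {
  D <- as.matrix(D)
  vapply(seq_along(cl), function(i) {
    mine <- which(cl == cl[i])
    if (length(mine) == 1) return(0)
    a <- mean(D[i, setdiff(mine, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(D[i, cl == k]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# the published 13-cluster membership (correlation + UPGMA), for the soft
# co-membership comparison
published_correlation_clusters <- function() {
  list(c("x1"), c("x2"), c("x3"), c("x4"), c("x5", "x9"),
       c("x6", "x8", "x41", "x42", "x43", "x44", "x45", "x46", "x47", "x48"),
       c("x7", "x20"), c("x10", "x13", "x21", "x24"),
       c("x11", "x12", "x16", "x17", "x22", "x23", "x27", "x28"),
       c("x14", "x15", "x25", "x26"), c("x18", "x19", "x29", "x30"),
       c("x31", "x36"),
       c("x32", "x33", "x34", "x35", "x37", "x38", "x39", "x40"))
}

pairwise_comembership_agreement <- function(cl, ref_clusters) {
  ref <- integer(length(cl))
  names(ref) <- names(cl)
  for (i in seq_along(ref_clusters)) ref[ref_clusters[[i]]] <- i
  idx <- utils::combn(length(cl), 2)
  a <- cl[idx[1, ]] == cl[idx[2, ]]
  b <- ref[idx[1, ]] == ref[idx[2, ]]
  mean(a == b)
}

# a minimal Snoopy SPPED document for the reader subset; `logical_pair`
# duplicates place pm as two Logic=1 copies bridging the two halves
write_toy_spped <- function(path, marking_conflict = FALSE) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<Snoopy version="2" revision="1.13">',
    '  <netclass name="Petri Net"/>',
    '  <nodeclasses count="2">',
    '    <nodeclass count="4" name="Place">',
    '      <node id="1"><attribute name="Name"><![CDATA[p0]]></attribute>',
    '        <attribute name="Marking">1</attribute>',
    '        <attribute name="Logic">0</attribute></node>',
    '      <node id="2"><attribute name="Name"><![CDATA[p1]]></attribute>',
    '        <attribute name="Marking">2</attribute>',
    '        <attribute name="Logic">1</attribute></node>',
    '      <node id="3"><attribute name="Name"><![CDATA[p1]]></attribute>',
    sprintf('        <attribute name="Marking">%d</attribute>',
            if (marking_conflict) 5L else 2L),
    '        <attribute name="Logic">1</attribute></node>',
    '      <node id="4"><attribute name="Name"><![CDATA[p2]]></attribute>',
    '        <attribute name="Marking">0</attribute>',
    '        <attribute name="Logic">0</attribute></node>',
    '    </nodeclass>',
    '    <nodeclass count="2" name="Transition">',
    '      <node id="5"><attribute name="Name"><![CDATA[t0]]></attribute></node>',
    '      <node id="6"><attribute name="Name"><![CDATA[t1]]></attribute></node>',
    '    </nodeclass>',
    '  </nodeclasses>',
    '  <edgeclasses count="1">',
    '    <edgeclass count="4" name="Edge">',
    '      <edge source="1" target="5"><attribute name="Multiplicity">1</attribute></edge>',
    '      <edge source="5" target="2"><attribute name="Multiplicity">1</attribute></edge>',
    '      <edge source="3" target="6"><attribute name="Multiplicity">1</attribute></edge>',
    '      <edge source="6" target="4"><attribute name="Multiplicity">1</attribute></edge>',
    '    </edgeclass>',
    '  </edgeclasses>',
    '</Snoopy>')
  writeLines(lines, path)
  path
}
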