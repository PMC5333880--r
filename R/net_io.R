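#' Read a Petri net from a file
#'
#' Supported dialects:
#' \describe{
#'   \item{spped}{Snoopy place/transition net XML (read-only subset: places,
#'     transitions, edges, markings, logical places). Logical (shadow) place
#'     copies — independent graphical elements that correspond to one net
#'     vertex — are merged into a single place; conflicting token counts
#'     within one logical group are an error.}
#'   \item{pnml}{ISO PNML, basic Place/Transition subset; unknown elements
#'     are ignored.}
#'   \item{json}{the native dialect written by [write_net()]:
#'     `{"places": [...], "transitions": [...], "arcs": [[src, dst, w], ...],
#'     "marking": {...}}`.}
#'   \item{incidence-csv}{an incidence matrix as written by [write_net()];
#'     reconstructs one arc per nonzero entry (sign = direction, magnitude =
#'     weight), so it can only represent pure nets and the reader refuses
#'     files flagged `# pure: false`.}
#' }
#'
#' @param path file path
#' @param format one of `"spped"`, `"pnml"`, `"json"`, `"incidence-csv"`;
#'   by default inferred from the file extension
#' @return a validated [petri_net()]
#' @export
read_net <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     spped = "spped", pnml = "pnml", xml = "pnml",
                     json = "json", csv = "incidence-csv",
                     stop("cannot infer format from extension of ", path))
  }
  format <- match.arg(format, c("spped", "pnml", "json", "incidence-csv"))
  switch(format,
         spped = read_spped(path),
         pnml = read_pnml(path),
         json = read_net_json(path),
         `incidence-csv` = read_incidence_csv(path))
}

#' Write a Petri net to a file
#'
#' Output is byte-stable for a fixed net (deterministic element ordering).
#' SPPED output is not supported (Snoopy's full schema is out of scope).
#'
#' @param net a `petri_net`
#' @param path output file path
#' @param format one of `"pnml"`, `"json"`, `"incidence-csv"`
#' @return `path`, invisibly
#' @export
write_net <- function(net, path, format = c("json", "pnml", "incidence-csv")) {
  stopifnot(inherits(net, "petri_net"))
  format <- match.arg(format)
  switch(format,
         json = write_net_json(net, path),
         pnml = write_pnml(net, path),
         `incidence-csv` = write_incidence_csv(net, path))
  invisible(path)
}

## ---- native JSON dialect ----

write_net_json <- function(net, path) {
  mk <- net$marking[net$marking > 0]
  obj <- list(
    places = unname(apply(net$places, 1, function(r) list(id = r[["id"]], name = r[["name"]]))),
    transitions = unname(apply(net$transitions, 1, function(r) list(id = r[["id"]], name = r[["name"]]))),
    arcs = unname(lapply(seq_len(nrow(net$arcs)), function(i)
      list(net$arcs$source[i], net$arcs$target[i], net$arcs$weight[i]))),
    marking = if (length(mk)) as.list(mk) else stats::setNames(list(), character())
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
}

read_net_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("unparseable JSON in ", path, ": ",
                                           conditionMessage(e)))
  node_df <- function(x) {
    if (!length(x)) return(character())
    if (is.character(x[[1]]) || is.null(names(x[[1]]))) {
      data.frame(id = vapply(x, function(e) as.character(e[[1]]), character(1)),
                 name = vapply(x, function(e) as.character(e[[length(e)]]), character(1)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = vapply(x, function(e) as.character(e$id), character(1)),
                 name = vapply(x, function(e) as.character(if (is.null(e$name)) e$id else e$name), character(1)),
                 stringsAsFactors = FALSE)
    }
  }
  arcs <- if (length(obj$arcs)) {
    data.frame(source = vapply(obj$arcs, function(a) as.character(a[[1]]), character(1)),
               target = vapply(obj$arcs, function(a) as.character(a[[2]]), character(1)),
               weight = vapply(obj$arcs, function(a)
                 if (length(a) >= 3) as.integer(a[[3]]) else 1L, integer(1)),
               stringsAsFactors = FALSE)
  } else NULL
  marking <- if (length(obj$marking)) unlist(obj$marking) else NULL
  petri_net(node_df(obj$places), node_df(obj$transitions), arcs, marking)
}

## ---- PNML ----

write_pnml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">',
             '  <net id="net1" type="http://www.pnml.org/version-2009/grammar/ptnet">',
             '    <page id="page1">')
  for (i in seq_len(nrow(net$places))) {
    id <- net$places$id[i]
    lines <- c(lines, sprintf('      <place id="%s">', esc(id)),
               sprintf('        <name><text>%s</text></name>', esc(net$places$name[i])))
    if (net$marking[[id]] > 0)
      lines <- c(lines, sprintf('        <initialMarking><text>%d</text></initialMarking>',
                                net$marking[[id]]))
    lines <- c(lines, '      </place>')
  }
  for (i in seq_len(nrow(net$transitions)))
    lines <- c(lines, sprintf('      <transition id="%s"><name><text>%s</text></name></transition>',
                              esc(net$transitions$id[i]), esc(net$transitions$name[i])))
  for (i in seq_len(nrow(net$arcs))) {
    a <- net$arcs[i, ]
    w <- if (a$weight != 1L)
      sprintf('<inscription><text>%d</text></inscription>', a$weight) else ""
    lines <- c(lines, sprintf('      <arc id="a%d" source="%s" target="%s">%s</arc>',
                              i, esc(a$source), esc(a$target), w))
  }
  lines <- c(lines, '    </page>', '  </net>', '</pnml>')
  writeLines(lines, path)
}

read_pnml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable XML in ", path, ": ",
                                           conditionMessage(e)))
  grab <- function(tag) xml2::xml_find_all(doc, sprintf(".//*[local-name()='%s']", tag))
  text_of <- function(node, tag) {
    hit <- xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']/*[local-name()='text']", tag))
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  pls <- grab("place")
  trs <- grab("transition")
  arcs <- grab("arc")
  pid <- xml2::xml_attr(pls, "id")
  pname <- vapply(pls, text_of, character(1), tag = "name")
  ptok <- vapply(pls, text_of, character(1), tag = "initialMarking")
  tid <- xml2::xml_attr(trs, "id")
  tname <- vapply(trs, text_of, character(1), tag = "name")
  adf <- if (length(arcs)) {
    w <- vapply(arcs, text_of, character(1), tag = "inscription")
    data.frame(source = xml2::xml_attr(arcs, "source"),
               target = xml2::xml_attr(arcs, "target"),
               weight = ifelse(is.na(w), 1L, as.integer(w)),
               stringsAsFactors = FALSE)
  } else NULL
  marking <- stats::setNames(as.integer(ifelse(is.na(ptok), 0L, as.integer(ptok))), pid)
  petri_net(data.frame(id = pid, name = ifelse(is.na(pname), pid, pname)),
            data.frame(id = tid, name = ifelse(is.na(tname), tid, tname)),
            adf, marking[marking > 0])
}

## ---- Snoopy SPPED (read-only subset) ----

read_spped <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable XML in ", path, ": ",
                                           conditionMessage(e)))
  attr_of <- function(node, name) {
    hit <- xml2::xml_find_first(node, sprintf("./attribute[@name='%s']", name))
    if (inherits(hit, "xml_missing")) NA_character_ else trimws(xml2::xml_text(hit))
  }
  nodes_of <- function(class) xml2::xml_find_all(
    doc, sprintf(".//nodeclass[@name='%s']/node", class))

  pnodes <- nodes_of("Place")
  tnodes <- nodes_of("Transition")
  if (!length(pnodes) && !length(tnodes))
    stop("no Place/Transition node classes found in ", path)

  read_nodes <- function(nodes) {
    data.frame(xml_id = xml2::xml_attr(nodes, "id"),
               name = vapply(nodes, attr_of, character(1), name = "Name"),
               marking = vapply(nodes, attr_of, character(1), name = "Marking"),
               logic = vapply(nodes, attr_of, character(1), name = "Logic"),
               stringsAsFactors = FALSE)
  }
  pd <- read_nodes(pnodes)
  td <- read_nodes(tnodes)
  pd$marking <- ifelse(is.na(pd$marking), 0L, as.integer(pd$marking))
  pd$logic <- !is.na(pd$logic) & pd$logic == "1"
  pd$name <- ifelse(is.na(pd$name) | pd$name == "", paste0("P", pd$xml_id), pd$name)
  td$name <- ifelse(is.na(td$name) | td$name == "", paste0("T", td$xml_id), td$name)

  # merge logical (shadow) place copies sharing a name into one vertex;
  # duplicate names among purely non-logical places are disambiguated instead
  pd$vertex <- pd$name
  nonlog <- !pd$logic
  dup <- nonlog & (duplicated(pd$name) | duplicated(pd$name, fromLast = TRUE)) &
    !(pd$name %in% pd$name[pd$logic])
  pd$vertex[dup] <- paste0(pd$name[dup], "#", pd$xml_id[dup])

  merged <- unique(pd$vertex)
  tokens <- vapply(merged, function(v) {
    tk <- unique(pd$marking[pd$vertex == v & pd$marking > 0])
    if (length(tk) > 1)
      stop("logical place group '", v, "' has conflicting token counts: ",
           paste(tk, collapse = ", "))
    if (length(tk)) tk else 0L
  }, integer(1))

  edges <- xml2::xml_find_all(doc, ".//edgeclass/edge")
  id_map <- c(stats::setNames(pd$vertex, pd$xml_id),
              stats::setNames(td$name, td$xml_id))
  adf <- NULL
  if (length(edges)) {
    w <- vapply(edges, attr_of, character(1), name = "Multiplicity")
    adf <- data.frame(source = id_map[xml2::xml_attr(edges, "source")],
                      target = id_map[xml2::xml_attr(edges, "target")],
                      weight = ifelse(is.na(w), 1L, as.integer(w)),
                      stringsAsFactors = FALSE)
    if (anyNA(adf$source) || anyNA(adf$target))
      stop("edge references unknown node id in ", path)
    # merged logical copies can duplicate an arc; identical duplicates collapse
    adf <- unique(adf)
    key <- paste(adf$source, adf$target)
    if (anyDuplicated(key))
      stop("conflicting duplicate arcs after logical-place merge: ",
           key[duplicated(key)][1])
  }
  petri_net(data.frame(id = merged, name = merged),
            data.frame(id = td$name, name = td$name),
            adf, tokens[tokens > 0])
}

## ---- incidence-matrix CSV ----

write_incidence_csv <- function(net, path) {
  A <- incidence_matrix(net)
  pure <- structural_report(net)$pure
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pure: %s", tolower(as.character(pure))), con)
  writeLines(paste(c("place", colnames(A)), collapse = ","), con)
  for (i in seq_len(nrow(A)))
    writeLines(paste(c(rownames(A)[i], A[i, ]), collapse = ","), con)
}

read_incidence_csv <- function(path) {
  first <- readLines(path, n = 1)
  skip <- 0L
  if (startsWith(first, "#")) {
    if (grepl("pure:\\s*false", first))
      stop("incidence CSV flagged as from a non-pure net; ",
           "read arcs cannot be reconstructed from an incidence matrix")
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        stringsAsFactors = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  net_from_incidence(A)
}

#' Reconstruct a pure Petri net from an incidence matrix
#'
#' One arc per nonzero entry: a positive entry becomes a transition-to-place
#' arc of that weight, a negative entry a place-to-transition arc. Read-arc
#' (self-loop) pairs cancel in an incidence matrix and cannot be recovered.
#'
#' @param A integer matrix, rows = places, columns = transitions (dimnames
#'   used as ids)
#' @param marking optional named initial marking
#' @return a `petri_net`
#' @export
net_from_incidence <- function(A, marking = NULL) {
  A <- as.matrix(A)
  if (is.null(rownames(A))) rownames(A) <- paste0("p", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("t", seq_len(ncol(A)))
  idx <- which(A != 0, arr.ind = TRUE)
  adf <- NULL
  if (nrow(idx)) {
    w <- A[idx]
    adf <- data.frame(
      source = ifelse(w > 0, colnames(A)[idx[, 2]], rownames(A)[idx[, 1]]),
      target = ifelse(w > 0, rownames(A)[idx[, 1]], colnames(A)[idx[, 2]]),
      weight = abs(w), stringsAsFactors = FALSE)
  }
  petri_net(rownames(A), colnames(A), adf, marking)
}

## ---- support matrix CSV ----

#' Read or write a t-invariant support matrix in simple CSV form
#'
#' The dialect: comma separator, header row `invariant,<transition labels>`,
#' one row per invariant starting with its label (`x1`, `x2`, ...), cells 0
#' or 1. `write_support_csv` followed by `read_support_csv` is the identity.
#'
#' @param path CSV file path
#' @return `read_support_csv`: binary integer matrix with invariant row
#'   labels and transition column labels, orders preserved from the file
#' @export
read_support_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(M %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(M))
    stop("non-binary cell at row ", rc[1], " ('", df[[1]][rc[1]], "'), column ",
         rc[2], " ('", colnames(M)[rc[2]], "'): ", M[bad[1]])
  }
  storage.mode(M) <- "integer"
  rownames(M) <- df[[1]]
  M
}

#' @rdname read_support_csv
#' @param support binary matrix (rows = invariants, columns = transitions)
#' @export
write_support_csv <- function(support, path) {
  support <- as.matrix(support)
  rl <- rownames(support)
  if (is.null(rl)) rl <- paste0("x", seq_len(nrow(support)))
  cl <- colnames(support)
  if (is.null(cl)) cl <- paste0("t", seq_len(ncol(support)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("invariant", cl), collapse = ","), con)
  for (i in seq_len(nrow(support)))
    writeLines(paste(c(rl[i], support[i, ]), collapse = ","), con)
  invisible(path)
}
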