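#' Construct a taxonomy tree
#'
#' A taxonomy is a rooted, labelled tree with a designated *focal clade*:
#' the taxon whose members are considered genuine for the assembly under
#' study (e.g. a phylum). Every classifier in the package maps taxa to one
#' of four labels relative to this clade: `FOCAL` (inside the clade),
#' `CONTAMINANT` (outside it), `UNKNOWN` (a strict ancestor of the clade,
#' i.e. a classification too high-ranking to be informative), or
#' `UNCLASSIFIED` (no taxon at all).
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`. Exactly one row (the root) must have `parent_id` `NA` or `""`.
#' @param focal_id taxon_id of the focal clade.
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(nodes, focal_id) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == ""] <- NA_character_

  if (anyDuplicated(nodes$taxon_id)) {
    dup <- nodes$taxon_id[duplicated(nodes$taxon_id)][1]
    stop("duplicate taxon_id: ", dup)
  }
  roots <- nodes$taxon_id[is.na(nodes$parent_id)]
  if (length(roots) != 1) {
    stop("taxonomy must have exactly one root, found ",
         length(roots), ": ", paste(roots, collapse = ", "))
  }
  missing_parent <- setdiff(nodes$parent_id[!is.na(nodes$parent_id)], nodes$taxon_id)
  if (length(missing_parent)) {
    stop("parent_id not in taxonomy: ", missing_parent[1])
  }

  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)

  # depth by iterative propagation from the root; failure to converge
  # means a parent chain loops
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$taxon_id)
  depth[roots] <- 0L
  repeat {
    todo <- is.na(depth) & !is.na(depth[parent[names(depth)]])
    if (!any(todo)) break
    depth[todo] <- depth[parent[names(depth)[todo]]] + 1L
  }
  if (anyNA(depth)) {
    stop("parent chain loops or is disconnected at node: ",
         names(depth)[is.na(depth)][1])
  }

  focal_id <- as.character(focal_id)
  if (!focal_id %in% nodes$taxon_id) stop("unknown focal_id: ", focal_id)

  tree <- structure(
    list(nodes = nodes, root_id = roots, focal_id = focal_id,
         parent = parent, depth = depth),
    class = "taxonomy"
  )
  # descendants of the focal clade (inclusive) and its strict ancestors,
  # precomputed once: label_of() is called on every read
  tree$focal_set <- descendants(tree, focal_id)
  anc <- ancestors(tree, focal_id)
  tree$focal_ancestors <- setdiff(anc, focal_id)
  tree
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, root '", x$root_id,
      "', focal clade '", x$focal_id, "' (",
      length(x$focal_set), " taxa)\n", sep = "")
  invisible(x)
}

assert_taxa <- function(tree, taxa) {
  bad <- setdiff(taxa, tree$nodes$taxon_id)
  if (length(bad)) stop("unknown taxon_id: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Root path of a taxon
#'
#' @param tree a [taxonomy()].
#' @param taxon_id a single taxon id.
#' @return Character vector of taxon ids from `taxon_id` up to the root
#'   (self first).
#' @export
ancestors <- function(tree, taxon_id) {
  assert_taxa(tree, taxon_id)
  path <- character(tree$depth[[taxon_id]] + 1L)
  cur <- taxon_id
  i <- 1L
  while (!is.na(cur)) {
    path[i] <- cur
    cur <- tree$parent[[cur]]
    i <- i + 1L
  }
  path
}

#' All taxa in the clade rooted at a taxon (inclusive)
#' @inheritParams ancestors
#' @export
descendants <- function(tree, taxon_id) {
  assert_taxa(tree, taxon_id)
  out <- taxon_id
  frontier <- taxon_id
  while (length(frontier)) {
    kids <- tree$nodes$taxon_id[tree$nodes$parent_id %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every input
#' taxon.
#'
#' @param tree a [taxonomy()].
#' @param taxa nonempty character vector of taxon ids.
#' @return A single taxon id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("lca() needs at least one taxon")
  assert_taxa(tree, taxa)
  if (length(taxa) == 1L) return(taxa)
  cur <- taxa[1]
  for (t in taxa[-1]) {
    a <- cur; b <- t
    da <- tree$depth[[a]]; db <- tree$depth[[b]]
    while (da > db) { a <- tree$parent[[a]]; da <- da - 1L }
    while (db > da) { b <- tree$parent[[b]]; db <- db - 1L }
    while (a != b) { a <- tree$parent[[a]]; b <- tree$parent[[b]] }
    cur <- a
    if (cur == tree$root_id) return(cur)
  }
  cur
}

#' Is `anc` an ancestor-or-self of `desc`?
#' @inheritParams ancestors
#' @param anc,desc single taxon ids.
#' @export
is_ancestor <- function(tree, anc, desc) {
  assert_taxa(tree, c(anc, desc))
  d <- tree$depth[[desc]] - tree$depth[[anc]]
  if (d < 0) return(FALSE)
  cur <- desc
  while (d > 0) { cur <- tree$parent[[cur]]; d <- d - 1L }
  cur == anc
}

#' Three-way labelling of taxa relative to the focal clade
#'
#' Maps each taxon to `FOCAL` (inside the focal clade, inclusive),
#' `UNKNOWN` (a strict ancestor of the focal clade: a classification such
#' as the bacterial root, informative about neither genuineness nor
#' contamination), or `CONTAMINANT` (anywhere else in the tree). `NA`
#' taxa map to `UNCLASSIFIED`.
#'
#' @param tree a [taxonomy()].
#' @param taxa character vector of taxon ids (NA allowed).
#' @return Character vector of labels, same length as `taxa`.
#' @export
label_of <- function(tree, taxa) {
  taxa <- as.character(taxa)
  assert_taxa(tree, taxa[!is.na(taxa)])
  out <- rep("CONTAMINANT", length(taxa))
  out[is.na(taxa)] <- "UNCLASSIFIED"
  out[taxa %in% tree$focal_set] <- "FOCAL"
  out[taxa %in% tree$focal_ancestors] <- "UNKNOWN"
  out
}

#' Nearest ancestor of a given rank
#'
#' Used for the per-phylum breakdown of assembly profiles: each classified
#' read is attributed to the phylum-rank ancestor of its taxon, if any.
#'
#' @param tree a [taxonomy()].
#' @param taxa character vector of taxon ids (NA allowed).
#' @param rank rank name to look for (default `"phylum"`).
#' @return Character vector of taxon ids (NA where no ancestor of that
#'   rank exists).
#' @export
rank_ancestor <- function(tree, taxa, rank = "phylum") {
  rk <- stats::setNames(tree$nodes$rank, tree$nodes$taxon_id)
  vapply(as.character(taxa), function(t) {
    if (is.na(t)) return(NA_character_)
    cur <- t
    while (!is.na(cur)) {
      if (rk[[cur]] == rank) return(cur)
      cur <- tree$parent[[cur]]
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read / write a taxonomy as 4-column TSV
#'
#' Format: `taxon_id<TAB>parent_id<TAB>rank<TAB>name`, UTF-8, `#` comment
#' lines allowed; the root row has an empty `parent_id`. Tree invariants
#' (single root, no cycles) are validated at load.
#'
#' @param path file path.
#' @param focal_id focal clade taxon id; if `NULL`, read from a
#'   `#focal_id=` header comment.
#' @return `read_taxonomy()` a [taxonomy()]; `write_taxonomy()` the path,
#'   invisibly.
#' @export
read_taxonomy <- function(path, focal_id = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#focal_id=", lines, value = TRUE)
  if (is.null(focal_id)) {
    if (!length(hdr)) stop("no focal_id given and no #focal_id= header in ", path)
    focal_id <- sub("^#focal_id=", "", hdr[1])
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4)) {
    stop("taxonomy TSV line ", which(nf != 4)[1], " has ", nf[nf != 4][1],
         " fields, expected 4")
  }
  m <- do.call(rbind, parts)
  nodes <- data.frame(taxon_id = m[, 1], parent_id = m[, 2],
                      rank = m[, 3], name = m[, 4],
                      stringsAsFactors = FALSE)
  taxonomy(nodes, focal_id)
}

#' @rdname read_taxonomy
#' @param tree a [taxonomy()].
#' @export
write_taxonomy <- function(tree, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#focal_id=", tree$focal_id), con)
  n <- tree$nodes
  p <- ifelse(is.na(n$parent_id), "", n$parent_id)
  writeLines(paste(n$taxon_id, p, n$rank, n$name, sep = "\t"), con)
  invisible(path)
}
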