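#' Build a Taxonomy from a concept table
#'
#' @param concepts data.frame with columns \code{id}, \code{label},
#'   \code{branch}, \code{parents} (list column or pipe-separated string).
#' @return a validated \linkS4class{Taxonomy}.
#' @export
Taxonomy <- function(concepts) {
  stopifnot(is.data.frame(concepts),
            all(c("id", "label", "branch", "parents") %in% names(concepts)))
  ids <- as.character(concepts$id)
  labels <- as.character(concepts$label)
  branches <- as.character(concepts$branch)
  parents <- concepts$parents
  if (!is.list(parents))
    parents <- lapply(as.character(parents), function(p) {
      p <- trimws(strsplit(p, "|", fixed = TRUE)[[1L]])
      p[nzchar(p)]
    })
  parents <- lapply(parents, as.character)
  names(parents) <- ids

  bad <- which(!grepl(CURIE_RE, ids))
  if (length(bad))
    stop("malformed concept id '", ids[bad[1L]], "' (record ", bad[1L], ")")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate concept id '", dup[1L], "'")
  for (i in seq_along(ids)) {
    missing <- setdiff(parents[[i]], ids)
    if (length(missing))
      stop("concept '", ids[i], "' references unknown parent '",
           missing[1L], "'")
  }

  cyc <- .findCycle(ids, parents)
  if (!is.null(cyc))
    stop("parent relation contains a cycle: ", paste(cyc, collapse = " -> "))

  anc <- .ancestorClosure(ids, parents)
  obj <- new("Taxonomy", ids = ids, labels = labels, branches = branches,
             parents = parents, ancestors = anc)
  validObject(obj)
  obj
}

# Depth-first search with colouring; returns one cycle (as an id path) or NULL.
.findCycle <- function(ids, parents) {
  colour <- integer(length(ids))      # 0 white, 1 grey, 2 black
  names(colour) <- ids
  path <- character(0)
  cycle <- NULL
  visit <- function(id) {
    if (!is.null(cycle)) return()
    colour[id] <<- 1L
    path <<- c(path, id)
    for (p in parents[[id]]) {
      if (colour[p] == 1L) {
        at <- match(p, path)
        cycle <<- c(path[at:length(path)], p)
        return()
      }
      if (colour[p] == 0L) visit(p)
      if (!is.null(cycle)) return()
    }
    colour[id] <<- 2L
    path <<- path[-length(path)]
  }
  for (id in ids) if (colour[id] == 0L) visit(id)
  cycle
}

# Reflexive-transitive closure over parents, memoised (acyclicity assumed).
.ancestorClosure <- function(ids, parents) {
  anc <- vector("list", length(ids))
  names(anc) <- ids
  get1 <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    res <- id
    for (p in parents[[id]]) res <- union(res, get1(p))
    anc[[id]] <<- res
    res
  }
  for (id in ids) get1(id)
  anc
}

#' Load a taxonomy from a file
#'
#' Two dialects are supported: a flattened tab-delimited table with columns
#' \code{id}, \code{label}, \code{branch}, \code{parents} (pipe-separated,
#' empty for a root), and a strict subset of OBO (\code{[Term]} stanzas with
#' \code{id:}, \code{name:} and \code{is_a:} lines; the branch is derived
#' from the curie prefix).
#'
#' @param path file path.
#' @param dialect \code{"table"} or \code{"obo"}.
#' @return a validated \linkS4class{Taxonomy}.
#' @export
loadTaxonomy <- function(path, dialect = c("table", "obo")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  if (dialect == "table") {
    df <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE, quote = "")
    need <- c("id", "label", "branch", "parents")
    if (!all(need %in% names(df)))
      stop("taxonomy table must have columns ", paste(need, collapse = ", "))
    Taxonomy(df)
  } else {
    .parseOboSubset(path)
  }
}

.parseOboSubset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) stop("OBO term stanza without an id (near line ",
                              cur$line, ")")
    terms[[length(terms) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") { flush(); cur <- list(line = i, is_a = character(0)) }
    else if (grepl("^\\[", ln)) { flush(); cur <- NULL }
    else if (!is.null(cur) && grepl("^id:", ln))
      cur$id <- trimws(sub("^id:", "", ln))
    else if (!is.null(cur) && grepl("^name:", ln))
      cur$name <- trimws(sub("^name:", "", ln))
    else if (!is.null(cur) && grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, tgt)
    }
  }
  flush()
  if (!length(terms)) stop("no [Term] stanzas found in ", path)
  df <- data.frame(
    id = vapply(terms, `[[`, character(1), "id"),
    label = vapply(terms, function(t) t$name %||% t$id, character(1)),
    stringsAsFactors = FALSE
  )
  df$branch <- curieBranch(df$id)
  df$parents <- lapply(terms, `[[`, "is_a")
  Taxonomy(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a taxonomy as a flattened table
#'
#' Inverse of \code{loadTaxonomy(..., dialect = "table")}; reloading the
#' written file yields an identical subsumption relation.
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  stopifnot(is(taxonomy, "Taxonomy"))
  df <- data.frame(
    id = taxonomy@ids, label = taxonomy@labels, branch = taxonomy@branches,
    parents = vapply(taxonomy@parents[taxonomy@ids], paste,
                     character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.checkConcept <- function(taxonomy, id) {
  if (!id %in% taxonomy@ids)
    stop("concept id '", id, "' does not resolve in the taxonomy")
  invisible(id)
}

#' Is-a subsumption query
#'
#' \code{TRUE} iff \code{ancestorId} is reachable from \code{childId} via
#' zero or more parent steps (reflexive and transitive).
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param childId,ancestorId concept curies.
#' @return logical scalar.
#' @export
isSubsumed <- function(taxonomy, childId, ancestorId) {
  .checkConcept(taxonomy, childId)
  .checkConcept(taxonomy, ancestorId)
  ancestorId %in% taxonomy@ancestors[[childId]]
}

#' All descendants of a concept
#'
#' The set of concept ids subsumed by \code{id}, including \code{id} itself.
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param id a concept curie.
#' @return character vector of curies.
#' @export
descendants <- function(taxonomy, id) {
  .checkConcept(taxonomy, id)
  taxonomy@ids[vapply(taxonomy@ancestors[taxonomy@ids],
                      function(a) id %in% a, logical(1))]
}

#' Concept ids of a taxonomy
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param branch optional branch filter.
#' @return character vector of curies.
#' @export
conceptIds <- function(taxonomy, branch = NULL) {
  if (is.null(branch)) return(taxonomy@ids)
  stopifnot(branch %in% BRANCHES)
  taxonomy@ids[taxonomy@branches == branch]
}

#' Preferred term of a concept
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param id concept curie.
#' @return character scalar label.
#' @export
conceptLabel <- function(taxonomy, id) {
  .checkConcept(taxonomy, id)
  taxonomy@labels[match(id, taxonomy@ids)]
}

#' Root concept of a branch
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param branch branch name.
#' @return curie of the branch root.
#' @export
branchRoot <- function(taxonomy, branch) {
  stopifnot(branch %in% BRANCHES)
  in.b <- taxonomy@branches == branch
  if (!any(in.b)) stop("taxonomy has no '", branch, "' branch")
  ids <- taxonomy@ids[in.b]
  ids[vapply(taxonomy@parents[ids], function(p) length(p) == 0L, logical(1))]
}

setMethod("show", "Taxonomy", function(object) {
  cat("Taxonomy with", length(object@ids), "concepts\n")
  tb <- table(object@branches)
  cat(paste0("  ", names(tb), ": ", as.integer(tb), collapse = "\n"), "\n")
})
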