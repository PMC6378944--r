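#' Build the automaton-like solution graph
#'
#' With \code{merge = TRUE} (solutions must share one length) nodes with the
#' same concrete data state at the same step index are collapsed, yielding
#' the compact automaton-like view in which every input-to-output path is a
#' valid workflow.  Merging is per step index, never global: the same state
#' reached at different depths stays distinct, which guarantees that the
#' dynamic-programming path count equals the number of solutions.  With
#' \code{merge = FALSE} each solution keeps its own chain of nodes.
#'
#' @param set a non-empty \linkS4class{SolutionSet}.
#' @param merge collapse identical states per step index?
#' @param taxonomy optional \linkS4class{Taxonomy}; if given, node labels
#'   are attached.
#' @return a \linkS4class{SolutionGraph}.
#' @export
buildSolutionGraph <- function(set, merge = TRUE, taxonomy = NULL) {
  sols <- set@solutions
  if (!length(sols)) stop("cannot build a graph from an empty solution set")
  lens <- vapply(sols, function(s) length(s@tools), integer(1))
  if (merge && length(unique(lens)) != 1L)
    stop("solutions have mixed lengths (", paste(sort(unique(lens)),
         collapse = ", "), "); filter to a fixed length before merging")
  nodeKey <- character(0)
  nodes <- list()
  edges <- list()
  addNode <- function(key, step, data, format) {
    at <- match(key, nodeKey)
    if (!is.na(at)) return(at)
    nodeKey[length(nodeKey) + 1L] <<- key
    nodes[[length(nodes) + 1L]] <<- data.frame(
      step = step, data = data, format = format, stringsAsFactors = FALSE)
    length(nodes)
  }
  for (si in seq_along(sols)) {
    s <- sols[[si]]
    st <- s@states
    prevIdx <- NULL
    for (i in seq_len(nrow(st))) {
      key <- if (merge) paste(i - 1L, st$data[i], st$format[i], sep = "|")
             else paste(si, i - 1L, st$data[i], st$format[i], sep = "|")
      idx <- addNode(key, i - 1L, st$data[i], st$format[i])
      if (i > 1L)
        edges[[length(edges) + 1L]] <- data.frame(
          from = prevIdx, to = idx, tool = s@tools[i - 1L],
          stringsAsFactors = FALSE)
      prevIdx <- idx
    }
  }
  ndf <- do.call(rbind, nodes)
  ndf$id <- seq_len(nrow(ndf))
  edf <- unique(do.call(rbind, edges))
  rownames(edf) <- NULL
  if (!is.null(taxonomy)) {
    ndf$dataLabel <- vapply(ndf$data, conceptLabel, character(1),
                            taxonomy = taxonomy)
    ndf$formatLabel <- vapply(ndf$format, conceptLabel, character(1),
                              taxonomy = taxonomy)
  }
  new("SolutionGraph", nodes = ndf, edges = edf,
      length = as.integer(if (merge) lens[1L] else max(lens)))
}

#' Count input-to-output paths of a merged solution graph
#'
#' Dynamic programming over step layers.  For a merged fixed-length graph
#' this equals the number of solutions it was built from.
#'
#' @param graph a \linkS4class{SolutionGraph}.
#' @return numeric path count.
#' @export
countPaths <- function(graph) {
  n <- graph@nodes
  e <- graph@edges
  ways <- numeric(nrow(n))
  ways[n$step == 0L] <- 1
  for (d in seq_len(graph@length)) {
    sel <- which(n$step[e$to] == d)
    w <- numeric(nrow(n))
    for (r in sel) w[e$to[r]] <- w[e$to[r]] + ways[e$from[r]]
    ways[n$step == d] <- w[n$step == d]
  }
  sum(ways[n$step == graph@length])
}

#' Enumerate all input-to-output paths of a solution graph
#'
#' @param graph a \linkS4class{SolutionGraph}.
#' @return list of lists with \code{tools} and \code{states} (data.frame),
#'   one per path.
#' @export
enumeratePaths <- function(graph) {
  n <- graph@nodes
  e <- graph@edges
  res <- list()
  walk <- function(node, toolsPath, dataPath, fmtPath) {
    step <- n$step[node]
    if (step == graph@length) {
      res[[length(res) + 1L]] <<- list(
        tools = toolsPath,
        states = data.frame(data = dataPath, format = fmtPath,
                            stringsAsFactors = FALSE))
      return()
    }
    outs <- which(e$from == node)
    outs <- outs[order(e$tool[outs], n$format[e$to[outs]])]
    for (r in outs)
      walk(e$to[r], c(toolsPath, e$tool[r]),
           c(dataPath, n$data[e$to[r]]), c(fmtPath, n$format[e$to[r]]))
  }
  for (src in which(n$step == 0L))
    walk(src, character(0), n$data[src], n$format[src])
  res
}

.dotQuote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Serialise a solution graph to DOT
#'
#' Deterministic (byte-stable) serialisation: nodes are sorted by step,
#' data, format; edges by step, endpoints and tool.  Node labels show the
#' data and format terms; edge labels show tool names.
#'
#' @param graph a \linkS4class{SolutionGraph}.
#' @return character scalar containing DOT source.
#' @export
toDot <- function(graph) {
  n <- graph@nodes
  ord <- order(n$step, n$data, n$format)
  n <- n[ord, , drop = FALSE]
  remap <- match(graph@nodes$id, n$id)
  e <- graph@edges
  e$from <- remap[e$from]; e$to <- remap[e$to]
  e <- e[order(e$from, e$to, e$tool), , drop = FALSE]
  hasLabels <- all(c("dataLabel", "formatLabel") %in% names(n))
  nodeLabel <- function(i) {
    if (hasLabels)
      paste0(n$dataLabel[i], " [", n$data[i], "]\\n",
             n$formatLabel[i], " [", n$format[i], "]")
    else paste0(n$data[i], "\\n", n$format[i])
  }
  lines <- c(
    "digraph solutions {",
    "  rankdir=LR;",
    "  node [shape=box];",
    vapply(seq_len(nrow(n)), function(i)
      paste0("  n", i, " [label=", .dotQuote(nodeLabel(i)), "];"),
      character(1)),
    vapply(seq_len(nrow(e)), function(r)
      paste0("  n", e$from[r], " -> n", e$to[r],
             " [label=", .dotQuote(e$tool[r]), "];"),
      character(1)),
    "}"
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Tabulate a solution set
#'
#' One row per solution: length, arrow-joined tool names, arrow-joined
#' format curies, in the set's canonical order.
#'
#' @param set a \linkS4class{SolutionSet}.
#' @return data.frame with columns \code{length}, \code{tools},
#'   \code{formats}.
#' @export
solutionsToTable <- function(set) {
  if (!length(set@solutions))
    return(data.frame(length = integer(0), tools = character(0),
                      formats = character(0), stringsAsFactors = FALSE))
  data.frame(
    length = vapply(set@solutions, function(s) length(s@tools), integer(1)),
    tools = vapply(set@solutions, function(s)
      paste(s@tools, collapse = " -> "), character(1)),
    formats = vapply(set@solutions, function(s)
      paste(s@states$format, collapse = " -> "), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Render a solution table as tab-delimited text
#' @param set a \linkS4class{SolutionSet}.
#' @return character scalar (header plus one line per solution).
#' @export
solutionTableText <- function(set) {
  df <- solutionsToTable(set)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Export a workflow skeleton
#'
#' One placeholder command line per tool, annotated with the input and
#' output states of the step.  The skeleton is explicitly not executable:
#' tool parameters must be supplied by the user.
#'
#' @param solution a \linkS4class{Solution}.
#' @param taxonomy optional \linkS4class{Taxonomy} for human-readable
#'   format labels in the comments.
#' @return character vector of script lines.
#' @export
exportSkeleton <- function(solution, taxonomy = NULL) {
  st <- solution@states
  lab <- function(id)
    if (is.null(taxonomy)) id
    else paste0(conceptLabel(taxonomy, id), " [", id, "]")
  lines <- c("#!/bin/sh",
             "# workflow skeleton -- NOT executable as-is:",
             "# supply tool parameters and real file names before running")
  for (i in seq_along(solution@tools)) {
    lines <- c(lines,
      paste0("# step ", i, ": in  = ", lab(st$data[i]), " / ",
             lab(st$format[i])),
      paste0("# step ", i, ": out = ", lab(st$data[i + 1L]), " / ",
             lab(st$format[i + 1L])),
      paste0(solution@tools[i], " <parameters> <input> <output>"))
  }
  lines
}

setMethod("show", "SolutionGraph", function(object) {
  cat("SolutionGraph:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges, length", object@length, "\n")
})
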