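#' Construct a WorkflowSpec
#'
#' @param initial initial \linkS4class{DataState}.
#' @param goalData goal data concept (class-level).
#' @param goalFormat goal format concept; the format branch root means
#'   "any format".
#' @param constraints list of \linkS4class{Constraint}.
#' @param maxLength positive length bound.
#' @param mode \code{"shortest_only"} or \code{"up_to_bound"}.
#' @return a validated \linkS4class{WorkflowSpec}.
#' @export
WorkflowSpec <- function(initial, goalData, goalFormat, constraints = list(),
                         maxLength = 4L, mode = c("shortest_only",
                                                  "up_to_bound")) {
  mode <- match.arg(mode)
  obj <- new("WorkflowSpec", initial = initial,
             goalData = as.character(goalData),
             goalFormat = as.character(goalFormat),
             constraints = constraints,
             maxLength = as.integer(maxLength), mode = mode)
  validObject(obj)
  obj
}

#' Load a workflow specification from JSON
#'
#' Schema: \code{\{"input": \{"data", "format"\}, "output": \{"data",
#' "format"\}, "constraints": [template strings], "max_length": n,
#' "mode": "shortest_only"|"up_to_bound"\}}.
#'
#' @param path JSON file path.
#' @param model a \linkS4class{DomainModel} (resolves constraint fillers).
#' @return a \linkS4class{WorkflowSpec}.
#' @export
loadWorkflowSpec <- function(path, model) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (fld in c("input", "output"))
    if (is.null(js[[fld]])) stop("spec file misses '", fld, "'")
  tax <- model@taxonomy
  ini <- DataState(unlist(js$input$data), unlist(js$input$format))
  .checkConcept(tax, ini@data); .checkConcept(tax, ini@format)
  gd <- unlist(js$output$data)
  gf <- unlist(js$output$format) %||% branchRoot(tax, "format")
  .checkConcept(tax, gd); .checkConcept(tax, gf)
  cons <- lapply(js$constraints %||% list(),
                 function(s) parseConstraint(unlist(s), model))
  WorkflowSpec(ini, gd, gf, cons,
               maxLength = js$max_length %||% 4L,
               mode = js$mode %||% "shortest_only")
}

#' Write a workflow specification as JSON
#' @param spec a \linkS4class{WorkflowSpec}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWorkflowSpec <- function(spec, path) {
  js <- list(
    input = list(data = spec@initial@data, format = spec@initial@format),
    output = list(data = spec@goalData, format = spec@goalFormat),
    constraints = lapply(spec@constraints, formatConstraint),
    max_length = spec@maxLength,
    mode = spec@mode
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Layered breadth-first search over the product of concrete data states and
# joint constraint-monitor states.  Paths entering any reject sink are pruned
# immediately; the frontier therefore never exceeds
# |data states| x prod(monitor states) entries per layer.

.synthSearch <- function(model, spec, maxDepth) {
  tax <- model@taxonomy
  cons <- c(spec@constraints, model@constraints)
  mons <- lapply(cons, compileMonitor)
  nC <- length(cons)
  toolnames <- sort(names(model@tools))
  tools <- model@tools[toolnames]
  nT <- length(tools)
  codes <- matrix(0L, nrow = nT, ncol = nC)
  if (nC && nT)
    for (k in seq_len(nC))
      codes[, k] <- vapply(tools, function(t)
        .monitorCode(cons[[k]], t, tax), integer(1))
  outFmts <- lapply(tools, function(t) sort(unique(t@output@formats)))

  goalAcc <- function(data, format)
    (spec@goalData %in% tax@ancestors[[data]]) &&
    (spec@goalFormat %in% tax@ancestors[[format]])
  monAcc <- function(ms) {
    for (k in seq_len(nC)) if (!mons[[k]]@accepting[ms[k]]) return(FALSE)
    TRUE
  }

  initMon <- vapply(mons, function(m) m@initial, integer(1))
  layers <- vector("list", maxDepth + 1L)
  edges <- vector("list", maxDepth)
  layers[[1L]] <- list(
    data = spec@initial@data, format = spec@initial@format,
    mon = matrix(initMon, nrow = 1L, ncol = nC)
  )

  for (d in seq_len(maxDepth)) {
    prev <- layers[[d]]
    nPrev <- length(prev$data)
    idx <- new.env(parent = emptyenv(), hash = TRUE)
    nd <- character(0); nf <- character(0); nmon <- list()
    ef <- integer(0); et <- character(0); eto <- integer(0)
    for (i in seq_len(nPrev)) {
      danc <- tax@ancestors[[prev$data[i]]]
      fanc <- tax@ancestors[[prev$format[i]]]
      ms <- prev$mon[i, , drop = TRUE]
      if (nC == 0L) ms <- integer(0)
      for (j in seq_len(nT)) {
        t <- tools[[j]]
        if (!(t@input@data %in% danc)) next
        if (!any(t@input@formats %in% fanc)) next
        newms <- ms
        pruned <- FALSE
        for (k in seq_len(nC)) {
          newms[k] <- mons[[k]]@transitions[ms[k], codes[j, k]]
          if (mons[[k]]@sink[newms[k]]) { pruned <- TRUE; break }
        }
        if (pruned) next
        for (f in outFmts[[j]]) {
          key <- paste(t@output@data, f, paste(newms, collapse = ","),
                       sep = "|")
          to <- idx[[key]]
          if (is.null(to)) {
            to <- length(nd) + 1L
            idx[[key]] <- to
            nd[to] <- t@output@data; nf[to] <- f
            nmon[[to]] <- newms
          }
          n <- length(ef) + 1L
          ef[n] <- i; et[n] <- toolnames[j]; eto[n] <- to
        }
      }
    }
    layers[[d + 1L]] <- list(
      data = nd, format = nf,
      mon = if (length(nmon)) do.call(rbind, nmon)
            else matrix(integer(0), nrow = 0L, ncol = nC)
    )
    edges[[d]] <- data.frame(from = ef, tool = et, to = eto,
                             stringsAsFactors = FALSE)
    if (!length(nd)) { maxDepth <- d; break }
  }
  layers <- layers[seq_len(maxDepth + 1L)]
  edges <- edges[seq_len(maxDepth)]

  accepting <- lapply(layers, function(ly) {
    if (!length(ly$data)) return(logical(0))
    vapply(seq_along(ly$data), function(i)
      goalAcc(ly$data[i], ly$format[i]) &&
        monAcc(if (nC) ly$mon[i, , drop = TRUE] else integer(0)),
      logical(1))
  })
  list(layers = layers, edges = edges, accepting = accepting,
       depth = maxDepth,
       exploredNodes = sum(vapply(layers, function(ly) length(ly$data),
                                  integer(1))))
}

# Per-length solution counts by forward dynamic programming (no enumeration).
.countByLengthDP <- function(search) {
  nL <- length(search$layers)
  ways <- vector("list", nL)
  ways[[1L]] <- 1
  counts <- numeric(nL)
  counts[1L] <- if (length(search$accepting[[1L]]) &&
                    search$accepting[[1L]][1L]) 1 else 0
  for (d in seq_len(nL - 1L)) {
    e <- search$edges[[d]]
    n <- length(search$layers[[d + 1L]]$data)
    w <- numeric(n)
    if (nrow(e))
      for (r in seq_len(nrow(e)))
        w[e$to[r]] <- w[e$to[r]] + ways[[d]][e$from[r]]
    ways[[d + 1L]] <- w
    acc <- search$accepting[[d + 1L]]
    counts[d + 1L] <- if (length(acc)) sum(w[acc]) else 0
  }
  stats::setNames(counts, as.character(seq_len(nL) - 1L))
}

#' Enumerate all workflows satisfying a specification
#'
#' Breadth-first search over the product of concrete data states and the
#' joint constraint-monitor state, pruning reject sinks, followed by
#' enumeration of every accepted path.  Solutions are state-annotated: the
#' same tool sequence routed through different intermediate formats counts
#' as distinct solutions.  In \code{"shortest_only"} mode only the smallest
#' length with at least one solution is returned; \code{"up_to_bound"}
#' returns all lengths up to the bound.
#'
#' @param model a \linkS4class{DomainModel}.
#' @param spec a \linkS4class{WorkflowSpec}.
#' @return a \linkS4class{SolutionSet}; empty (with the searched depth
#'   recorded) when the bound is exhausted without a solution.
#' @export
synthesize <- function(model, spec) {
  validObject(spec)
  sr <- .synthSearch(model, spec, spec@maxLength)
  accDepths <- which(vapply(sr$accepting, any, logical(1))) - 1L
  if (!length(accDepths))
    return(new("SolutionSet", solutions = list(), spec = spec,
               countsByLength = stats::setNames(integer(0), character(0)),
               exploredNodes = as.integer(sr$exploredNodes),
               searchDepth = as.integer(sr$depth)))
  targets <- if (spec@mode == "shortest_only") accDepths[1L] else accDepths
  searchDepth <- if (spec@mode == "shortest_only") targets else sr$depth

  # backward viability: can this node begin a suffix ending at a target depth?
  nL <- length(sr$layers)
  lead <- vector("list", nL)
  for (d in rev(seq_len(nL))) {
    depth <- d - 1L
    acc <- sr$accepting[[d]]
    v <- logical(length(sr$layers[[d]]$data))
    if (depth %in% targets) v <- v | acc
    if (d < nL) {
      e <- sr$edges[[d]]
      nxt <- lead[[d + 1L]]
      if (nrow(e))
        for (r in seq_len(nrow(e)))
          if (nxt[e$to[r]]) v[e$from[r]] <- TRUE
    }
    lead[[d]] <- v
  }

  sols <- list()
  emit <- function(toolsPath, dataPath, fmtPath) {
    sols[[length(sols) + 1L]] <<- new("Solution",
      tools = toolsPath,
      states = data.frame(data = dataPath, format = fmtPath,
                          stringsAsFactors = FALSE))
  }
  maxTarget <- max(targets)
  walk <- function(d, node, toolsPath, dataPath, fmtPath) {
    depth <- d - 1L
    if ((depth %in% targets) && sr$accepting[[d]][node])
      emit(toolsPath, dataPath, fmtPath)
    if (depth >= maxTarget || d >= nL) return()
    e <- sr$edges[[d]]
    if (!nrow(e)) return()
    mine <- which(e$from == node)
    for (r in mine) {
      to <- e$to[r]
      if (!lead[[d + 1L]][to]) next
      walk(d + 1L, to,
           c(toolsPath, e$tool[r]),
           c(dataPath, sr$layers[[d + 1L]]$data[to]),
           c(fmtPath, sr$layers[[d + 1L]]$format[to]))
    }
  }
  walk(1L, 1L, character(0), spec@initial@data, spec@initial@format)

  # canonical ordering: (length, tool names, state format ids)
  keys <- vapply(sols, function(s)
    paste(sprintf("%04d", length(s@tools)),
          paste(s@tools, collapse = "\r"),
          paste(s@states$format, collapse = "\r"), sep = "\n"),
    character(1))
  if (anyDuplicated(keys2 <- vapply(sols, function(s)
        paste(paste(s@tools, collapse = "\r"),
              paste(s@states$data, s@states$format, collapse = "\r"),
              sep = "\n"), character(1))))
    stop("internal error: duplicate solutions enumerated")
  sols <- sols[order(keys, method = "radix")]

  lens <- vapply(sols, function(s) length(s@tools), integer(1))
  tb <- table(factor(lens, levels = sort(unique(lens))))
  new("SolutionSet", solutions = sols, spec = spec,
      countsByLength = stats::setNames(as.integer(tb), names(tb)),
      exploredNodes = as.integer(sr$exploredNodes),
      searchDepth = as.integer(searchDepth))
}

#' Minimal solution length for a specification
#'
#' @param model a \linkS4class{DomainModel}.
#' @param spec a \linkS4class{WorkflowSpec} (its own bound and mode are
#'   ignored).
#' @param cap maximal length to try.
#' @return smallest length with at least one solution, or \code{NA} if none
#'   exists within \code{cap}.
#' @export
findMinLength <- function(model, spec, cap = spec@maxLength) {
  stopifnot(cap >= 1L)
  sr <- .synthSearch(model, spec, as.integer(cap))
  accDepths <- which(vapply(sr$accepting, any, logical(1))) - 1L
  if (!length(accDepths)) return(NA_integer_)
  as.integer(accDepths[1L])
}

#' Number of solutions in a set
#' @param set a \linkS4class{SolutionSet}.
#' @return integer.
#' @export
solutionCount <- function(set) length(set@solutions)

#' Solutions of a set
#' @param set a \linkS4class{SolutionSet}.
#' @return list of \linkS4class{Solution}.
#' @export
solutions <- function(set) set@solutions

#' Per-length solution counts
#' @param set a \linkS4class{SolutionSet}.
#' @return named integer vector (names are lengths).
#' @export
countsByLength <- function(set) set@countsByLength

#' Distinct tool sequences of a solution set
#'
#' Collapses state-annotated solutions to unique tool-name sequences (the
#' alternative counting mode).
#'
#' @param set a \linkS4class{SolutionSet}.
#' @return list of character vectors, in canonical order.
#' @export
uniqueToolSequences <- function(set) {
  seqs <- lapply(set@solutions, function(s) s@tools)
  keys <- vapply(seqs, function(s)
    paste(sprintf("%04d", length(s)), paste(s, collapse = "\r"), sep = "\n"),
    character(1))
  seqs[!duplicated(keys)][order(unique(keys), method = "radix")]
}

#' Validate a candidate solution against a specification
#'
#' Independent checker (used by tests and the command-line interface): it
#' re-derives every invariant from first principles — step compatibility,
#' declared output states, goal subsumption, and the declarative trace
#' semantics of all specification and global constraints — without going
#' through the synthesis search.
#'
#' @param model a \linkS4class{DomainModel}.
#' @param spec a \linkS4class{WorkflowSpec}.
#' @param candidate a \linkS4class{Solution}.
#' @return list with elements \code{valid} (logical) and \code{violations}
#'   (character vector naming each violated invariant or constraint).
#' @export
validateSolution <- function(model, spec, candidate) {
  v <- character(0)
  tax <- model@taxonomy
  st <- candidate@states
  n <- length(candidate@tools)
  if (st$data[1L] != spec@initial@data ||
      st$format[1L] != spec@initial@format)
    v <- c(v, "initial state differs from the specification input")
  for (i in seq_len(n)) {
    nm <- candidate@tools[i]
    t <- model@tools[[nm]]
    if (is.null(t)) { v <- c(v, paste0("unknown tool '", nm, "'")); next }
    cur <- DataState(st$data[i], st$format[i])
    if (!compatible(t, cur, tax))
      v <- c(v, paste0("step ", i, ": tool '", nm,
                       "' is not applicable in state (", cur@data, ", ",
                       cur@format, ")"))
    if (st$data[i + 1L] != t@output@data ||
        !st$format[i + 1L] %in% t@output@formats)
      v <- c(v, paste0("step ", i, ": state after '", nm,
                       "' is not a declared output of the tool"))
  }
  fin <- n + 1L
  if (!(spec@goalData %in% tax@ancestors[[st$data[fin]]]) ||
      !(spec@goalFormat %in% tax@ancestors[[st$format[fin]]]))
    v <- c(v, "final state does not satisfy the goal under subsumption")
  for (cn in c(spec@constraints, model@constraints)) {
    ok <- tryCatch(evaluateTrace(cn, candidate@tools, model),
                   error = function(e) FALSE)
    if (!ok)
      v <- c(v, paste0("constraint violated: ", formatConstraint(cn)))
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Lift a tool-name sequence to a state-annotated solution
#'
#' Searches over the tools' declared output formats for a state assignment
#' under which the sequence is a valid solution of the specification.  If
#' none exists, the first format-feasible assignment (or the structural
#' failure) is reported instead so violations can be named.
#'
#' @param model a \linkS4class{DomainModel}.
#' @param spec a \linkS4class{WorkflowSpec}.
#' @param toolsSeq character vector of tool names.
#' @return list with \code{solution} (a \linkS4class{Solution} or
#'   \code{NULL}), \code{valid}, and \code{violations}.
#' @export
workflowFromTools <- function(model, spec, toolsSeq) {
  unknown <- setdiff(toolsSeq, names(model@tools))
  if (length(unknown)) stop("unknown tool name '", unknown[1L], "'")
  tax <- model@taxonomy
  n <- length(toolsSeq)
  assigns <- list()
  rec <- function(i, dataPath, fmtPath) {
    if (i > n) {
      assigns[[length(assigns) + 1L]] <<- list(data = dataPath,
                                               format = fmtPath)
      return()
    }
    t <- model@tools[[toolsSeq[i]]]
    cur <- DataState(dataPath[i], fmtPath[i])
    if (!compatible(t, cur, tax)) return()
    for (f in sort(t@output@formats))
      rec(i + 1L, c(dataPath, t@output@data), c(fmtPath, f))
  }
  rec(1L, spec@initial@data, spec@initial@format)
  if (!length(assigns)) {
    # constraints only read tool names, so they can still be reported
    v <- paste0("no format-compatible state assignment exists for: ",
                paste(toolsSeq, collapse = " -> "))
    for (cn in c(spec@constraints, model@constraints))
      if (!evaluateTrace(cn, toolsSeq, model))
        v <- c(v, paste0("constraint violated: ", formatConstraint(cn)))
    return(list(solution = NULL, valid = FALSE, violations = v))
  }
  best <- NULL
  for (a in assigns) {
    cand <- new("Solution", tools = toolsSeq,
                states = data.frame(data = a$data, format = a$format,
                                    stringsAsFactors = FALSE))
    res <- validateSolution(model, spec, cand)
    if (res$valid)
      return(list(solution = cand, valid = TRUE, violations = character(0)))
    if (is.null(best)) best <- list(solution = cand, valid = FALSE,
                                    violations = res$violations)
  }
  best
}

setMethod("show", "WorkflowSpec", function(object) {
  cat("WorkflowSpec\n",
      " input:  (", object@initial@data, ",", object@initial@format, ")\n",
      " goal:   (", object@goalData, ",", object@goalFormat, ")\n",
      " bound:  ", object@maxLength, " mode:", object@mode, "\n",
      " constraints:", length(object@constraints), "\n")
  for (cn in object@constraints) cat("   -", formatConstraint(cn), "\n")
})

setMethod("show", "Solution", function(object) {
  cat("Solution (length", length(object@tools), "):",
      paste(object@tools, collapse = " -> "), "\n")
})

setMethod("show", "SolutionSet", function(object) {
  cat("SolutionSet:", length(object@solutions), "solution(s)\n")
  if (length(object@countsByLength)) {
    cat("  per length:",
        paste(names(object@countsByLength), object@countsByLength,
              sep = ": ", collapse = ", "), "\n")
  } else {
    cat("  no solutions within bound; searched depth",
        object@searchDepth, "\n")
  }
  cat("  product nodes explored:", object@exploredNodes, "\n")
})
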