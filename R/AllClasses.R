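#' @import methods
NULL

CURIE_RE <- "^(operation|data|format|topic):[0-9]+$"
BRANCHES <- c("operation", "data", "format", "topic")

curieBranch <- function(id) sub(":.*$", "", id)

#' Taxonomy: an EDAM-style is-a DAG
#'
#' Concepts carry a curie-style identifier (\code{"operation:3631"}), a
#' preferred term, a branch (operation, data, format or topic) and zero or
#' more parent concepts in the same branch.  Subsumption is reachability over
#' the parent relation; the transitive closure is precomputed at construction
#' so that \code{\link{isSubsumed}} is a constant-time lookup.
#'
#' @slot ids character vector of concept curies (unique).
#' @slot labels preferred terms, parallel to \code{ids}.
#' @slot branches branch of each concept, parallel to \code{ids}.
#' @slot parents named list: concept id -> character vector of parent ids.
#' @slot ancestors named list: concept id -> all ancestor ids including the
#'   concept itself (the reflexive-transitive closure of the parent relation).
#' @exportClass Taxonomy
setClass("Taxonomy", slots = c(
  ids       = "character",
  labels    = "character",
  branches  = "character",
  parents   = "list",
  ancestors = "list"
))

setValidity("Taxonomy", function(object) {
  msgs <- character()
  ids <- object@ids
  if (anyDuplicated(ids))
    msgs <- c(msgs, paste0("duplicate concept id: ",
                           ids[duplicated(ids)][1L]))
  bad <- !grepl(CURIE_RE, ids)
  if (any(bad))
    msgs <- c(msgs, paste0("malformed concept id: ", ids[bad][1L]))
  if (length(object@labels) != length(ids) ||
      length(object@branches) != length(ids))
    msgs <- c(msgs, "ids, labels and branches must have equal length")
  if (!all(object@branches %in% BRANCHES))
    msgs <- c(msgs, "unknown branch name")
  if (!identical(object@branches, curieBranch(ids)))
    msgs <- c(msgs, "branch must agree with the curie prefix")
  for (i in seq_along(ids)) {
    ps <- object@parents[[ids[i]]]
    missing <- setdiff(ps, ids)
    if (length(missing))
      msgs <- c(msgs, paste0("dangling parent id '", missing[1L],
                             "' of concept '", ids[i], "'"))
    else if (length(ps) &&
             !all(object@branches[match(ps, ids)] == object@branches[i]))
      msgs <- c(msgs, paste0("parent of '", ids[i],
                             "' lies in a different branch"))
  }
  # one root (concept without parents) per branch present
  if (!length(msgs)) {
    for (b in unique(object@branches)) {
      in.b <- object@branches == b
      roots <- ids[in.b][vapply(object@parents[ids[in.b]],
                                function(p) length(p) == 0L, logical(1))]
      if (length(roots) != 1L)
        msgs <- c(msgs, paste0("branch '", b, "' must have exactly one root, found ",
                               length(roots)))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PortSpec: a typed tool port
#'
#' A single input or output port: one data concept and one or more format
#' concepts the port accepts or produces.
#'
#' @slot data a data-branch curie.
#' @slot formats non-empty character vector of format-branch curies.
#' @exportClass PortSpec
setClass("PortSpec", slots = c(data = "character", formats = "character"))

setValidity("PortSpec", function(object) {
  if (length(object@data) != 1L) return("a port has exactly one data concept")
  if (length(object@formats) < 1L) return("a port needs at least one format")
  if (curieBranch(object@data) != "data")
    return(paste0("port data concept '", object@data, "' is not in the data branch"))
  bad <- curieBranch(object@formats) != "format"
  if (any(bad))
    return(paste0("port format concept '", object@formats[bad][1L],
                  "' is not in the format branch"))
  TRUE
})

#' ToolAnnotation: a semantically annotated tool
#'
#' @slot name unique tool identifier.
#' @slot operations non-empty character vector of operation-branch curies.
#' @slot input,output \linkS4class{PortSpec} objects (exactly one of each;
#'   multi-port tools are outside the pipelining model).
#' @exportClass ToolAnnotation
setClass("ToolAnnotation", slots = c(
  name = "character", operations = "character",
  input = "PortSpec", output = "PortSpec"
))

setValidity("ToolAnnotation", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("tool name must be a single non-empty string")
  if (length(object@operations) < 1L)
    return(paste0("tool '", object@name, "' needs at least one operation"))
  bad <- curieBranch(object@operations) != "operation"
  if (any(bad))
    return(paste0("tool '", object@name, "': '", object@operations[bad][1L],
                  "' is not an operation-branch concept"))
  TRUE
})

#' DataState: a concrete data item
#'
#' The single item flowing through a linear pipeline: a data concept in one
#' concrete format.
#'
#' @slot data a data-branch curie.
#' @slot format a format-branch curie (concrete, not a class).
#' @exportClass DataState
setClass("DataState", slots = c(data = "character", format = "character"))

setValidity("DataState", function(object) {
  if (length(object@data) != 1L || length(object@format) != 1L)
    return("a data state has exactly one data and one format concept")
  if (curieBranch(object@data) != "data")
    return(paste0("'", object@data, "' is not a data-branch concept"))
  if (curieBranch(object@format) != "format")
    return(paste0("'", object@format, "' is not a format-branch concept"))
  TRUE
})

#' Atom: a constraint filler
#'
#' Either a concrete tool (matched by name) or an operation class (matched
#' against a tool's annotated operations under subsumption).
#'
#' @slot kind \code{"tool"} or \code{"operation"}.
#' @slot ref tool name or operation curie.
#' @exportClass Atom
setClass("Atom", slots = c(kind = "character", ref = "character"))

setValidity("Atom", function(object) {
  if (!object@kind %in% c("tool", "operation")) return("unknown atom kind")
  if (object@kind == "operation" && !grepl("^operation:[0-9]+$", object@ref))
    return(paste0("operation atom ref '", object@ref, "' is not an operation curie"))
  TRUE
})

CONSTRAINT_FORMS <- c("USE", "AVOID", "ONLY_AFTER", "AT_MOST_ONCE",
                      "NO_IMMEDIATE_REPEAT")

#' Constraint: a finite-trace temporal property
#'
#' One of five template forms interpreted over finite tool traces:
#' \describe{
#'   \item{USE(A)}{some step matches A ("use A").}
#'   \item{AVOID(A)}{no step matches A ("do not use A").}
#'   \item{ONLY_AFTER(A, B)}{every step matching A is strictly preceded by a
#'     step matching B ("use A only after B").}
#'   \item{AT_MOST_ONCE(A)}{at most one step matches A ("do not use A more
#'     than once").}
#'   \item{NO_IMMEDIATE_REPEAT(A)}{no two consecutive steps both match A
#'     ("do not use A directly after A").}
#' }
#'
#' @slot form one of the five form names above.
#' @slot atoms list of \linkS4class{Atom}: one atom, or an ordered pair (A, B)
#'   for ONLY_AFTER.
#' @exportClass Constraint
setClass("Constraint", slots = c(form = "character", atoms = "list"))

setValidity("Constraint", function(object) {
  if (!object@form %in% CONSTRAINT_FORMS) return("unknown constraint form")
  want <- if (object@form == "ONLY_AFTER") 2L else 1L
  if (length(object@atoms) != want)
    return(paste0(object@form, " takes ", want, " atom(s)"))
  if (!all(vapply(object@atoms, is, logical(1), "Atom")))
    return("constraint atoms must be Atom objects")
  TRUE
})

#' ConstraintMonitor: a deterministic finite-state monitor
#'
#' The executable form of a \linkS4class{Constraint}: a total deterministic
#' automaton over per-step atom truth values whose acceptance on every finite
#' trace equals the declarative semantics (\code{\link{evaluateTrace}}).
#' Transition columns are indexed by an input code: \code{1 + mA} for
#' single-atom forms, \code{1 + mA + 2*mB} for ONLY_AFTER, where \code{mA},
#' \code{mB} are 0/1 atom truth values for the current step.
#'
#' @slot constraint the source \linkS4class{Constraint}.
#' @slot nStates number of monitor states.
#' @slot initial initial state index.
#' @slot accepting logical vector over states.
#' @slot sink logical vector: non-accepting states that cannot be left
#'   (used for pruning during synthesis).
#' @slot transitions integer matrix \code{nStates x nCodes}.
#' @exportClass ConstraintMonitor
setClass("ConstraintMonitor", slots = c(
  constraint = "Constraint",
  nStates = "integer", initial = "integer",
  accepting = "logical", sink = "logical",
  transitions = "matrix"
))

setValidity("ConstraintMonitor", function(object) {
  n <- object@nStates
  if (object@initial < 1L || object@initial > n) return("initial state out of range")
  if (length(object@accepting) != n || length(object@sink) != n)
    return("accepting/sink must have one entry per state")
  tr <- object@transitions
  if (nrow(tr) != n) return("transition matrix must have nStates rows")
  if (any(tr < 1L | tr > n)) return("transition target out of range")
  if (any(object@sink & object@accepting)) return("a sink state cannot accept")
  TRUE
})

#' DomainModel: taxonomy + annotated tools + global constraints
#'
#' @slot taxonomy a \linkS4class{Taxonomy}.
#' @slot tools named list of \linkS4class{ToolAnnotation} (unique names,
#'   list names equal tool names).
#' @slot constraints list of global \linkS4class{Constraint} objects applied
#'   to every synthesis run.
#' @slot edamVersion version string recorded in the model file.
#' @exportClass DomainModel
setClass("DomainModel", slots = c(
  taxonomy = "Taxonomy", tools = "list",
  constraints = "list", edamVersion = "character"
))

setValidity("DomainModel", function(object) {
  tls <- object@tools
  if (length(tls)) {
    if (!all(vapply(tls, is, logical(1), "ToolAnnotation")))
      return("tools must be ToolAnnotation objects")
    nms <- vapply(tls, function(t) t@name, character(1))
    if (anyDuplicated(nms))
      return(paste0("duplicate tool name: ", nms[duplicated(nms)][1L]))
    if (!identical(names(tls), unname(nms)))
      return("tools list must be named by tool name")
    # all referenced concepts must resolve with the right branch
    tax <- object@taxonomy
    for (t in tls) {
      for (id in c(t@operations, t@input@data, t@input@formats,
                   t@output@data, t@output@formats)) {
        if (!id %in% tax@ids)
          return(paste0("tool '", t@name, "' references unknown concept '",
                        id, "'"))
      }
    }
  }
  if (length(object@constraints) &&
      !all(vapply(object@constraints, is, logical(1), "Constraint")))
    return("global constraints must be Constraint objects")
  TRUE
})

#' WorkflowSpec: what the synthesized pipeline must achieve
#'
#' @slot initial the concrete initial \linkS4class{DataState}.
#' @slot goalData goal data concept (class-level; satisfied under subsumption).
#' @slot goalFormat goal format concept; the format root means "any format".
#' @slot constraints list of \linkS4class{Constraint}.
#' @slot maxLength positive length bound for the search.
#' @slot mode \code{"shortest_only"} (keep only the first length with
#'   solutions) or \code{"up_to_bound"} (all lengths up to the bound).
#' @exportClass WorkflowSpec
setClass("WorkflowSpec", slots = c(
  initial = "DataState", goalData = "character", goalFormat = "character",
  constraints = "list", maxLength = "integer", mode = "character"
))

setValidity("WorkflowSpec", function(object) {
  if (length(object@maxLength) != 1L || is.na(object@maxLength) ||
      object@maxLength < 1L)
    return("maxLength must be a positive integer")
  if (!object@mode %in% c("shortest_only", "up_to_bound"))
    return("mode must be 'shortest_only' or 'up_to_bound'")
  if (curieBranch(object@goalData) != "data")
    return("goalData must be a data-branch concept")
  if (curieBranch(object@goalFormat) != "format")
    return("goalFormat must be a format-branch concept")
  if (length(object@constraints) &&
      !all(vapply(object@constraints, is, logical(1), "Constraint")))
    return("constraints must be Constraint objects")
  TRUE
})

#' Solution: one state-annotated pipeline
#'
#' @slot tools ordered tool names, length n.
#' @slot states data.frame with columns \code{data}, \code{format} and
#'   n + 1 rows: the initial state followed by the state after each step.
#' @exportClass Solution
setClass("Solution", slots = c(tools = "character", states = "data.frame"))

setValidity("Solution", function(object) {
  st <- object@states
  if (!all(c("data", "format") %in% names(st)))
    return("states needs 'data' and 'format' columns")
  if (nrow(st) != length(object@tools) + 1L)
    return("states must have length(tools) + 1 rows")
  TRUE
})

#' SolutionSet: all solutions of a synthesis run
#'
#' @slot solutions list of \linkS4class{Solution}, sorted by (length, tool
#'   names, state format ids).
#' @slot spec the \linkS4class{WorkflowSpec} that was solved.
#' @slot countsByLength named integer vector: solutions per length.
#' @slot exploredNodes number of distinct product-automaton nodes expanded.
#' @slot searchDepth depth actually searched (equals the bound, or the
#'   minimal solution length in shortest-only mode).
#' @exportClass SolutionSet
setClass("SolutionSet", slots = c(
  solutions = "list", spec = "WorkflowSpec",
  countsByLength = "integer", exploredNodes = "integer",
  searchDepth = "integer"
))

#' SolutionGraph: automaton-like merged view of a solution set
#'
#' Nodes are concrete data states at a step index; edges are tool
#' applications.  For merged fixed-length sets, every input-to-output path is
#' a valid workflow and the dynamic-programming path count equals the number
#' of solutions.
#'
#' @slot nodes data.frame: \code{id}, \code{step}, \code{data}, \code{format},
#'   optional \code{dataLabel}/\code{formatLabel}.
#' @slot edges data.frame: \code{from}, \code{to} (node ids), \code{tool}.
#' @slot length common solution length (steps) for merged graphs.
#' @exportClass SolutionGraph
setClass("SolutionGraph", slots = c(
  nodes = "data.frame", edges = "data.frame", length = "integer"
))

#' RandomDomainConfig: parameters of the random model generator
#'
#' @slot seed integer seed; generation is a pure function of the config.
#' @slot nTools,nData,nFormats,nOperations component counts.
#' @slot maxFormatsPerPort maximal number of formats on a port.
#' @slot depth depth of the random taxonomy trees.
#' @exportClass RandomDomainConfig
setClass("RandomDomainConfig", slots = c(
  seed = "integer", nTools = "integer", nData = "integer",
  nFormats = "integer", nOperations = "integer",
  maxFormatsPerPort = "integer", depth = "integer"
))

setValidity("RandomDomainConfig", function(object) {
  for (s in c("nData", "nFormats", "nOperations", "maxFormatsPerPort", "depth"))
    if (slot(object, s) < 1L) return(paste0(s, " must be positive"))
  if (object@nTools < 0L) return("nTools must be non-negative")
  TRUE
})
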