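#' Construct an Atom
#' @param kind \code{"tool"} or \code{"operation"}.
#' @param ref tool name or operation curie.
#' @return an \linkS4class{Atom}.
#' @export
Atom <- function(kind, ref) {
  obj <- new("Atom", kind = kind, ref = as.character(ref))
  validObject(obj)
  obj
}

#' Construct a Constraint
#' @param form one of USE, AVOID, ONLY_AFTER, AT_MOST_ONCE,
#'   NO_IMMEDIATE_REPEAT.
#' @param atoms list of \linkS4class{Atom} (one, or an ordered pair for
#'   ONLY_AFTER).
#' @return a \linkS4class{Constraint}.
#' @export
Constraint <- function(form, atoms) {
  if (is(atoms, "Atom")) atoms <- list(atoms)
  obj <- new("Constraint", form = form, atoms = atoms)
  validObject(obj)
  obj
}

# Resolve a constraint filler to an Atom: a curie resolves as an operation
# concept, a tool name as a tool atom; otherwise a unique operation-branch
# label (case-insensitive) is accepted.
.resolveAtom <- function(text, model) {
  text <- trimws(text)
  tax <- model@taxonomy
  if (grepl(CURIE_RE, text)) {
    if (curieBranch(text) != "operation")
      stop("constraint filler '", text, "' must be an operation concept")
    .checkConcept(tax, text)
    return(Atom("operation", text))
  }
  if (text %in% names(model@tools)) return(Atom("tool", text))
  op.ids <- conceptIds(tax, "operation")
  hit <- op.ids[tolower(tax@labels[match(op.ids, tax@ids)]) == tolower(text)]
  if (length(hit) == 1L) return(Atom("operation", hit))
  if (length(hit) > 1L)
    stop("constraint filler '", text, "' is ambiguous: ",
         paste(hit, collapse = ", "))
  stop("constraint filler '", text,
       "' resolves to neither a tool nor an operation concept")
}

#' Parse a natural-language constraint template
#'
#' Five templates are recognised (case-insensitive keywords):
#' \itemize{
#'   \item \code{"use <A>"}
#'   \item \code{"do not use <A>"}
#'   \item \code{"use <A> only after <B>"}
#'   \item \code{"do not use <A> more than once"}
#'   \item \code{"do not use <A> directly after <A>"}
#' }
#' Fillers are tool names, operation curies, or unambiguous operation labels.
#'
#' @param text template string.
#' @param model a \linkS4class{DomainModel} used to resolve fillers.
#' @return a \linkS4class{Constraint}.
#' @export
parseConstraint <- function(text, model) {
  s <- trimws(text)
  m <- regmatches(s, regexec("^use\\s+(.+?)\\s+only\\s+after\\s+(.+)$", s,
                             ignore.case = TRUE))[[1L]]
  if (length(m))
    return(Constraint("ONLY_AFTER", list(.resolveAtom(m[2L], model),
                                         .resolveAtom(m[3L], model))))
  m <- regmatches(s, regexec(
    "^do\\s+not\\s+use\\s+(.+?)\\s+more\\s+than\\s+once$", s,
    ignore.case = TRUE))[[1L]]
  if (length(m))
    return(Constraint("AT_MOST_ONCE", list(.resolveAtom(m[2L], model))))
  m <- regmatches(s, regexec(
    "^do\\s+not\\s+use\\s+(.+?)\\s+directly\\s+after\\s+(.+)$", s,
    ignore.case = TRUE))[[1L]]
  if (length(m)) {
    a <- .resolveAtom(m[2L], model)
    b <- .resolveAtom(m[3L], model)
    if (!identical(a, b))
      stop("'do not use A directly after A' requires the same filler twice, ",
           "got '", m[2L], "' and '", m[3L], "'")
    return(Constraint("NO_IMMEDIATE_REPEAT", list(a)))
  }
  m <- regmatches(s, regexec("^do\\s+not\\s+use\\s+(.+)$", s,
                             ignore.case = TRUE))[[1L]]
  if (length(m))
    return(Constraint("AVOID", list(.resolveAtom(m[2L], model))))
  m <- regmatches(s, regexec("^use\\s+(.+)$", s, ignore.case = TRUE))[[1L]]
  if (length(m))
    return(Constraint("USE", list(.resolveAtom(m[2L], model))))
  stop("unrecognised constraint template: '", text, "'")
}

#' Render a constraint back to its template string
#' @param constraint a \linkS4class{Constraint}.
#' @return character scalar.
#' @export
formatConstraint <- function(constraint) {
  a <- vapply(constraint@atoms, function(x) x@ref, character(1))
  switch(constraint@form,
         USE = paste0("use ", a[1L]),
         AVOID = paste0("do not use ", a[1L]),
         ONLY_AFTER = paste0("use ", a[1L], " only after ", a[2L]),
         AT_MOST_ONCE = paste0("do not use ", a[1L], " more than once"),
         NO_IMMEDIATE_REPEAT = paste0("do not use ", a[1L],
                                      " directly after ", a[1L]))
}

#' Does a tool match a constraint atom?
#'
#' Tool atoms match by exact name; operation atoms match when some annotated
#' operation of the tool is a descendant-or-equal of the atom's concept.
#'
#' @param atom an \linkS4class{Atom}.
#' @param tool a \linkS4class{ToolAnnotation}.
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @return logical scalar.
#' @export
atomMatches <- function(atom, tool, taxonomy) {
  if (atom@kind == "tool") return(identical(atom@ref, tool@name))
  any(vapply(tool@operations,
             function(op) atom@ref %in% taxonomy@ancestors[[op]],
             logical(1)))
}

#' Evaluate a constraint on a finite tool trace
#'
#' Declarative finite-trace semantics (see \linkS4class{Constraint}).  The
#' empty trace satisfies every form except USE.
#'
#' @param constraint a \linkS4class{Constraint}.
#' @param trace character vector of tool names.
#' @param model a \linkS4class{DomainModel}.
#' @return logical scalar.
#' @export
evaluateTrace <- function(constraint, trace, model) {
  unknown <- setdiff(trace, names(model@tools))
  if (length(unknown)) stop("unknown tool name '", unknown[1L], "' in trace")
  tax <- model@taxonomy
  matchv <- function(atom)
    vapply(trace, function(nm) atomMatches(atom, model@tools[[nm]], tax),
           logical(1), USE.NAMES = FALSE)
  a <- matchv(constraint@atoms[[1L]])
  switch(constraint@form,
    USE = any(a),
    AVOID = !any(a),
    ONLY_AFTER = {
      b <- matchv(constraint@atoms[[2L]])
      # every position matching A is strictly preceded by some B position
      all(!a | (cumsum(c(0L, b))[seq_along(a)] > 0L))
    },
    AT_MOST_ONCE = sum(a) <= 1L,
    NO_IMMEDIATE_REPEAT = {
      n <- length(a)
      n < 2L || !any(a[-n] & a[-1L])
    })
}

#' Compile a constraint into a deterministic monitor
#'
#' The monitor's acceptance on every finite trace equals
#' \code{\link{evaluateTrace}}.  State counts: USE and AVOID use 2 states,
#' the other forms 3 (including a reject sink where applicable).
#'
#' @param constraint a \linkS4class{Constraint}.
#' @return a \linkS4class{ConstraintMonitor}.
#' @export
compileMonitor <- function(constraint) {
  # codes for single-atom forms: 1 = atom false, 2 = atom true
  # codes for ONLY_AFTER:        1 + mA + 2*mB
  mk <- function(n, init, acc, sink, tr) {
    storage.mode(tr) <- "integer"
    new("ConstraintMonitor", constraint = constraint,
        nStates = as.integer(n), initial = as.integer(init),
        accepting = acc, sink = sink, transitions = tr)
  }
  mon <- switch(constraint@form,
    USE = mk(2, 1, c(FALSE, TRUE), c(FALSE, FALSE),
             rbind(c(1, 2),
                   c(2, 2))),
    AVOID = mk(2, 1, c(TRUE, FALSE), c(FALSE, TRUE),
               rbind(c(1, 2),
                     c(2, 2))),
    ONLY_AFTER =
      # 1: B not seen yet; 2: B seen; 3: reject sink.  A step matching both
      # A and B with no earlier B still violates ("strictly preceded").
      mk(3, 1, c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
         rbind(c(1, 3, 2, 3),
               c(2, 2, 2, 2),
               c(3, 3, 3, 3))),
    AT_MOST_ONCE = mk(3, 1, c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
                      rbind(c(1, 2),
                            c(2, 3),
                            c(3, 3))),
    NO_IMMEDIATE_REPEAT =
      # 1: previous step did not match; 2: previous step matched; 3: sink
      mk(3, 1, c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
         rbind(c(1, 2),
               c(1, 3),
               c(3, 3))))
  validObject(mon)
  mon
}

#' Run a monitor over a trace of atom truth values
#'
#' @param monitor a \linkS4class{ConstraintMonitor}.
#' @param codes integer vector of per-step input codes (see
#'   \linkS4class{ConstraintMonitor}).
#' @return \code{TRUE} iff the final state accepts.
#' @export
runMonitor <- function(monitor, codes) {
  s <- monitor@initial
  for (cd in codes) s <- monitor@transitions[s, cd]
  monitor@accepting[s]
}

# Per-step input code of a tool for a constraint (trace-independent).
.monitorCode <- function(constraint, tool, taxonomy) {
  mA <- atomMatches(constraint@atoms[[1L]], tool, taxonomy)
  if (constraint@form == "ONLY_AFTER") {
    mB <- atomMatches(constraint@atoms[[2L]], tool, taxonomy)
    1L + as.integer(mA) + 2L * as.integer(mB)
  } else {
    1L + as.integer(mA)
  }
}

#' Monitor acceptance of a tool-name trace
#'
#' Convenience wrapper: computes per-step codes for the trace and runs the
#' compiled monitor.  Used as the executable counterpart of
#' \code{\link{evaluateTrace}}.
#'
#' @param monitor a \linkS4class{ConstraintMonitor}.
#' @param trace character vector of tool names.
#' @param model a \linkS4class{DomainModel}.
#' @return logical scalar.
#' @export
monitorAccepts <- function(monitor, trace, model) {
  codes <- vapply(trace, function(nm)
    .monitorCode(monitor@constraint, getTool(model, nm), model@taxonomy),
    integer(1), USE.NAMES = FALSE)
  runMonitor(monitor, codes)
}

setMethod("show", "Constraint", function(object) {
  cat("Constraint:", formatConstraint(object), "\n")
})

setMethod("show", "ConstraintMonitor", function(object) {
  cat("ConstraintMonitor for:", formatConstraint(object@constraint),
      "(", object@nStates, "states )\n")
})
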