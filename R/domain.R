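#' Construct a PortSpec
#' @param data data-branch curie.
#' @param formats character vector of format-branch curies.
#' @return a \linkS4class{PortSpec}.
#' @export
PortSpec <- function(data, formats) {
  obj <- new("PortSpec", data = as.character(data),
             formats = as.character(formats))
  validObject(obj)
  obj
}

#' Construct a ToolAnnotation
#' @param name tool name.
#' @param operations operation-branch curies.
#' @param input,output \linkS4class{PortSpec} objects.
#' @return a \linkS4class{ToolAnnotation}.
#' @export
ToolAnnotation <- function(name, operations, input, output) {
  obj <- new("ToolAnnotation", name = as.character(name),
             operations = as.character(operations),
             input = input, output = output)
  validObject(obj)
  obj
}

#' Construct a DataState
#' @param data data-branch curie.
#' @param format format-branch curie.
#' @return a \linkS4class{DataState}.
#' @export
DataState <- function(data, format) {
  obj <- new("DataState", data = as.character(data),
             format = as.character(format))
  validObject(obj)
  obj
}

#' Construct a DomainModel
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param tools list of \linkS4class{ToolAnnotation}.
#' @param constraints list of global \linkS4class{Constraint} objects.
#' @param edamVersion version string of the taxonomy the annotations target.
#' @return a validated \linkS4class{DomainModel}.
#' @export
DomainModel <- function(taxonomy, tools = list(), constraints = list(),
                        edamVersion = "1.18") {
  names(tools) <- vapply(tools, function(t) t@name, character(1))
  obj <- new("DomainModel", taxonomy = taxonomy, tools = tools,
             constraints = constraints, edamVersion = edamVersion)
  validObject(obj)
  obj
}

#' Tool names of a model
#' @param model a \linkS4class{DomainModel}.
#' @return character vector.
#' @export
toolNames <- function(model) names(model@tools)

#' Look up a tool annotation by name
#' @param model a \linkS4class{DomainModel}.
#' @param name tool name.
#' @return a \linkS4class{ToolAnnotation}.
#' @export
getTool <- function(model, name) {
  t <- model@tools[[name]]
  if (is.null(t)) stop("unknown tool name '", name, "'")
  t
}

#' Global constraints of a model
#' @param model a \linkS4class{DomainModel}.
#' @return list of \linkS4class{Constraint}.
#' @export
globalConstraints <- function(model) model@constraints

#' Load a domain model from JSON
#'
#' Schema: top-level object with \code{edam_version}, \code{tools} (array of
#' \{\code{name}, \code{operations[]}, \code{input}\{\code{data},
#' \code{formats[]}\}, \code{output}\{...\}\}) and \code{constraints} (array
#' of template strings, see \code{\link{parseConstraint}}).  Every concept
#' reference is checked against the taxonomy; an \code{edam_version}
#' different from the taxonomy's is a warning, not an error.
#'
#' @param path JSON file path.
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param taxonomyVersion version of the loaded taxonomy, compared against
#'   the file's \code{edam_version}.
#' @return a validated \linkS4class{DomainModel}.
#' @export
loadDomainModel <- function(path, taxonomy, taxonomyVersion = "1.18") {
  if (!file.exists(path)) stop("domain-model file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- js$edam_version %||% "unspecified"
  if (!identical(ver, taxonomyVersion))
    warning("domain model targets EDAM version '", ver,
            "' but the loaded taxonomy is version '", taxonomyVersion, "'")
  tools <- lapply(js$tools, function(tj) {
    nm <- tj$name
    if (is.null(nm) || !nzchar(nm)) stop("tool record without a name")
    port <- function(pj, field) {
      if (is.null(pj))
        stop("tool '", nm, "': missing ", field, " port")
      if (is.list(pj$data) || length(unlist(pj$data)) != 1L)
        stop("tool '", nm, "': ", field, " port must have exactly one data concept")
      PortSpec(unlist(pj$data), unlist(pj$formats))
    }
    ToolAnnotation(nm, unlist(tj$operations),
                   port(tj$input, "input"), port(tj$output, "output"))
  })
  nms <- vapply(tools, function(t) t@name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate tool name '", nms[duplicated(nms)][1L], "'")
  # concept resolution with field-level messages before class validity
  for (t in tools) {
    chk <- function(ids, field, branch) {
      for (id in ids) {
        if (!id %in% taxonomy@ids)
          stop("tool '", t@name, "', field '", field,
               "': unknown concept '", id, "'")
        if (curieBranch(id) != branch)
          stop("tool '", t@name, "', field '", field, "': concept '", id,
               "' is not in the ", branch, " branch")
      }
    }
    chk(t@operations, "operations", "operation")
    chk(t@input@data, "input.data", "data")
    chk(t@input@formats, "input.formats", "format")
    chk(t@output@data, "output.data", "data")
    chk(t@output@formats, "output.formats", "format")
  }
  model <- DomainModel(taxonomy, tools, list(), edamVersion = ver)
  cons <- lapply(js$constraints %||% list(),
                 function(s) parseConstraint(unlist(s), model))
  model@constraints <- cons
  validObject(model)
  model
}

#' Write a domain model as JSON
#'
#' Round-trips with \code{\link{loadDomainModel}}.
#'
#' @param model a \linkS4class{DomainModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDomainModel <- function(model, path) {
  js <- list(
    edam_version = model@edamVersion,
    tools = lapply(unname(model@tools), function(t) list(
      name = t@name,
      operations = as.list(t@operations),
      input = list(data = t@input@data, formats = as.list(t@input@formats)),
      output = list(data = t@output@data, formats = as.list(t@output@formats))
    )),
    constraints = lapply(model@constraints, formatConstraint)
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Can a tool be applied in a data state?
#'
#' A tool is applicable when the state's data concept is subsumed by the
#' tool's declared input data concept and the state's concrete format is
#' subsumed by at least one declared input format.  Tools declare classes;
#' states are concrete, so the state must be a descendant-or-equal of the
#' declaration.
#'
#' @param tool a \linkS4class{ToolAnnotation}.
#' @param state a \linkS4class{DataState}.
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @return logical scalar.
#' @export
compatible <- function(tool, state, taxonomy) {
  anc <- taxonomy@ancestors[[state@data]]
  if (is.null(anc)) .checkConcept(taxonomy, state@data)
  if (!tool@input@data %in% anc) return(FALSE)
  fanc <- taxonomy@ancestors[[state@format]]
  if (is.null(fanc)) .checkConcept(taxonomy, state@format)
  any(tool@input@formats %in% fanc)
}

#' All one-step successors of a data state
#'
#' One entry per (applicable tool, declared output format); the successor
#' state is the tool's output data concept in that concrete format.  The
#' result is sorted by tool name, then successor format id, so enumeration
#' is reproducible.
#'
#' @param model a \linkS4class{DomainModel}.
#' @param state a \linkS4class{DataState}.
#' @return data.frame with columns \code{tool}, \code{data}, \code{format}.
#' @export
successors <- function(model, state) {
  out <- list()
  for (nm in sort(names(model@tools))) {
    t <- model@tools[[nm]]
    if (compatible(t, state, model@taxonomy)) {
      for (f in sort(t@output@formats))
        out[[length(out) + 1L]] <- data.frame(
          tool = nm, data = t@output@data, format = f,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(tool = character(0), data = character(0),
                      format = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

setMethod("show", "DomainModel", function(object) {
  cat("DomainModel:", length(object@tools), "tools,",
      length(object@constraints), "global constraint(s),",
      "EDAM", object@edamVersion, "\n")
  if (length(object@tools))
    cat("  tools:", paste(utils::head(sort(names(object@tools)), 8L),
                          collapse = ", "),
        if (length(object@tools) > 8L) "..." else "", "\n")
})

setMethod("show", "ToolAnnotation", function(object) {
  cat("Tool", object@name, "\n",
      " operations:", paste(object@operations, collapse = ", "), "\n",
      " input: ", object@input@data, "[",
      paste(object@input@formats, collapse = ", "), "]\n",
      " output:", object@output@data, "[",
      paste(object@output@formats, collapse = ", "), "]\n")
})

setMethod("show", "DataState", function(object) {
  cat("DataState:", object@data, "/", object@format, "\n")
})
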