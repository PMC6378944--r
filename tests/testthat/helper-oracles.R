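# Shared fixtures and independent oracles used across the suite.

# -- tiny hand-built taxonomy -------------------------------------------------

tinyTaxonomyTable <- function() {
  data.frame(
    id = c("operation:1", "operation:2", "operation:3",
           "data:1", "data:2", "data:3",
           "format:1", "format:2", "format:3", "format:4"),
    label = c("op root", "op A", "op B",
              "data root", "data A", "data B",
              "fmt root", "fmt A", "fmt B", "fmt B1"),
    branch = c(rep("operation", 3), rep("data", 3), rep("format", 4)),
    parents = c("", "operation:1", "operation:2",
                "", "data:1", "data:1",
                "", "format:1", "format:1", "format:3"),
    stringsAsFactors = FALSE
  )
}

tinyTaxonomy <- function() Taxonomy(tinyTaxonomyTable())

# one tool mapping (data:2, format:2) -> (data:3, format:4)
tinyModel <- function(constraints = list()) {
  tax <- tinyTaxonomy()
  m <- DomainModel(tax, list(
    ToolAnnotation("alpha", "operation:2",
                   PortSpec("data:2", "format:2"),
                   PortSpec("data:3", "format:4"))
  ), list())
  m@constraints <- constraints
  m
}

# -- naive reachability oracle for subsumption -------------------------------

# recomputes ancestor reachability by plain breadth-first search over the
# parent lists, independent of the precomputed closure
naiveReachable <- function(taxonomy, childId, ancestorId) {
  frontier <- childId
  seen <- character(0)
  while (length(frontier)) {
    if (ancestorId %in% frontier) return(TRUE)
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(taxonomy@parents[frontier])), seen)
  }
  FALSE
}

# -- random DAG taxonomy (independent of randomDomain) -----------------------

randomDagTable <- function(seed, n = 12L) {
  set.seed(seed)
  ids <- sprintf("data:%d", 100L + seq_len(n))
  parents <- vector("list", n)
  parents[[1L]] <- character(0)
  for (i in seq_len(n)[-1L]) {
    k <- sample(1:2, 1L, prob = c(0.7, 0.3))
    k <- min(k, i - 1L)
    parents[[i]] <- ids[sample(seq_len(i - 1L), k)]
  }
  data.frame(id = ids, label = ids, branch = "data",
             parents = vapply(parents, paste, "", collapse = "|"),
             stringsAsFactors = FALSE)
}

# -- brute-force synthesis oracle --------------------------------------------

# enumerates every tool/state sequence up to the bound by plain recursion and
# filters with the declarative Solution invariants (compatible +
# evaluateTrace + goal subsumption); no monitors, no pruning
bruteForceSolutions <- function(model, spec) {
  tax <- model@taxonomy
  nms <- sort(names(model@tools))
  out <- list()
  goalOK <- function(d, f)
    isSubsumed(tax, d, spec@goalData) && isSubsumed(tax, f, spec@goalFormat)
  consOK <- function(trace) {
    for (cn in c(spec@constraints, model@constraints))
      if (!evaluateTrace(cn, trace, model)) return(FALSE)
    TRUE
  }
  rec <- function(toolsPath, dataPath, fmtPath) {
    n <- length(toolsPath)
    if (goalOK(dataPath[n + 1L], fmtPath[n + 1L]) && consOK(toolsPath))
      out[[length(out) + 1L]] <<- list(tools = toolsPath, data = dataPath,
                                       format = fmtPath)
    if (n == spec@maxLength) return()
    st <- DataState(dataPath[n + 1L], fmtPath[n + 1L])
    for (nm in nms) {
      t <- model@tools[[nm]]
      if (!compatible(t, st, tax)) next
      for (f in sort(t@output@formats))
        rec(c(toolsPath, nm), c(dataPath, t@output@data), c(fmtPath, f))
    }
  }
  rec(character(0), spec@initial@data, spec@initial@format)
  if (spec@mode == "shortest_only" && length(out)) {
    lens <- vapply(out, function(s) length(s$tools), integer(1))
    out <- out[lens == min(lens)]
  }
  out
}

solutionKey <- function(tools, formats)
  paste(sprintf("%04d", length(tools)), paste(tools, collapse = "\r"),
        paste(formats, collapse = "\r"), sep = "\n")

solutionSetKeys <- function(set)
  sort(vapply(solutions(set), function(s)
    solutionKey(s@tools, s@states$format), character(1)))

bruteForceKeys <- function(brute)
  sort(vapply(brute, function(s) solutionKey(s$tools, s$format), character(1)))

# random specification against a random model, for the oracle comparisons
randomSpecFor <- function(model, seed, maxLength = 4L) {
  set.seed(seed)
  tax <- model@taxonomy
  dataIds <- conceptIds(tax, "data")
  fmtIds <- conceptIds(tax, "format")
  one <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  tools <- names(model@tools)
  mkAtom <- function() {
    if (length(tools) && stats::runif(1) < 0.5) Atom("tool", one(tools))
    else Atom("operation", one(conceptIds(tax, "operation")))
  }
  nCons <- sample(0:2, 1L)
  cons <- lapply(seq_len(nCons), function(i) {
    form <- sample(c("USE", "AVOID", "ONLY_AFTER", "AT_MOST_ONCE",
                     "NO_IMMEDIATE_REPEAT"), 1L)
    if (form == "ONLY_AFTER") Constraint(form, list(mkAtom(), mkAtom()))
    else Constraint(form, list(mkAtom()))
  })
  # bias the initial state towards some tool's declared input so that the
  # search space is non-trivial reasonably often
  ini <- if (length(tools) && stats::runif(1) < 0.7) {
    t <- model@tools[[one(tools)]]
    DataState(t@input@data, one(t@input@formats))
  } else DataState(one(dataIds), one(fmtIds))
  WorkflowSpec(ini, one(dataIds), one(fmtIds), cons,
               maxLength = maxLength, mode = "up_to_bound")
}

# listed pipelines for the four bundled use cases
listedWorkflows <- function() {
  list(
    list(uc = 1L, tools = c("msconvert", "Comet", "PeptideProphet", "rt4")),
    list(uc = 1L, tools = c("msconvert", "Comet", "PeptideProphet",
                            "xml2tsv", "SSRCalc")),
    list(uc = 1L, tools = c("msconvert", "X! Tandem", "Tandem2XML",
                            "PeptideProphet", "rt4")),
    list(uc = 1L, tools = c("msconvert", "X! Tandem", "Tandem2XML",
                            "PeptideProphet", "xml2tsv", "SSRCalc")),
    list(uc = 2L, tools = c("msconvert", "Comet", "PeptideProphet",
                            "ProteinProphet", "extract_protein_names",
                            "GeneTrail2")),
    list(uc = 2L, tools = c("msconvert", "Comet", "PeptideProphet",
                            "ProteinProphet", "extract_protein_names",
                            "EnrichNet")),
    list(uc = 2L, tools = c("msconvert", "Comet", "PeptideProphet",
                            "ProteinProphet", "extract_protein_names",
                            "gProfileR")),
    list(uc = 3L, tools = c("msconvert", "Comet", "PeptideProphet",
                            "PTMProphet")),
    list(uc = 3L, tools = c("msconvert", "SearchGUI", "PeptideShaker_VPSM",
                            "PeptideShaker_PTMI")),
    list(uc = 4L, tools = c("msconvert", "SearchGUI", "PeptideShaker_VPSM",
                            "isobar")),
    list(uc = 4L, tools = c("msconvert", "Comet", "PeptideProphet", "Libra"))
  )
}

# cache the bundled fixtures once per test run
fixtureModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- proteomicsDomain()
    cache
  }
})

fixtureSpec <- function(uc, maxLength = NULL,
                        mode = c("up_to_bound", "shortest_only")) {
  mode <- match.arg(mode)
  spec <- useCaseSpec(uc, fixtureModel())
  if (!is.null(maxLength)) spec@maxLength <- as.integer(maxLength)
  spec@mode <- mode
  spec
}
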