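test_that("the bundled domain model loads, validates and names all key tools", {
  model <- fixtureModel()
  expect_s4_class(model, "DomainModel")
  expect_gte(length(toolNames(model)), 20L)
  expect_true(all(c("msconvert", "idconvert", "Comet", "X! Tandem",
                    "Tandem2XML", "PeptideProphet", "ProteinProphet",
                    "PTMProphet", "xml2tsv", "SSRCalc", "rt4",
                    "extract_protein_names", "GeneTrail2", "EnrichNet",
                    "gProfileR", "SearchGUI", "PeptideShaker_VPSM",
                    "PeptideShaker_PTMI", "isobar", "Libra")
                  %in% toolNames(model)))
  gc <- globalConstraints(model)
  expect_length(gc, 2L)
  expect_setequal(vapply(gc, function(c) c@form, character(1)),
                  "NO_IMMEDIATE_REPEAT")
  expect_setequal(vapply(gc, function(c) c@atoms[[1L]]@ref, character(1)),
                  c("msconvert", "idconvert"))
})

test_that("degenerate and malformed domain-model files are handled", {
  tax <- tinyTaxonomy()
  f <- withr::local_tempfile(fileext = ".json")

  jsonlite::write_json(list(edam_version = "1.18", tools = list(),
                            constraints = list()),
                       f, auto_unbox = TRUE)
  empty <- loadDomainModel(f, tax)
  expect_length(toolNames(empty), 0L)

  tool <- function(name, fmtIn = "format:2", fmtOut = "format:4",
                   op = "operation:2")
    list(name = name, operations = list(op),
         input = list(data = "data:2", formats = list(fmtIn)),
         output = list(data = "data:3", formats = list(fmtOut)))

  jsonlite::write_json(list(edam_version = "1.18",
                            tools = list(tool("a", fmtIn = "format:9"))),
                       f, auto_unbox = TRUE)
  expect_error(loadDomainModel(f, tax), "'a'.*input\\.formats.*format:9")

  jsonlite::write_json(list(edam_version = "1.18",
                            tools = list(tool("a"), tool("a"))),
                       f, auto_unbox = TRUE)
  expect_error(loadDomainModel(f, tax), "duplicate tool name")

  # a topic-branch concept can never serve as a port format
  jsonlite::write_json(list(edam_version = "1.18",
                            tools = list(tool("a", fmtIn = "topic:7"))),
                       f, auto_unbox = TRUE)
  expect_error(loadDomainModel(f, tax), "topic:7")

  jsonlite::write_json(list(edam_version = "1.17", tools = list(tool("a"))),
                       f, auto_unbox = TRUE)
  expect_warning(loadDomainModel(f, tax), "1\\.17")
})

test_that("tool applicability follows descendant-or-equal matching", {
  model <- fixtureModel()
  tax <- model@taxonomy
  raw <- DataState("data:0943", "format:3712")
  expect_true(compatible(getTool(model, "msconvert"), raw, tax))
  # search engines require a converted open format, not vendor RAW
  expect_false(compatible(getTool(model, "Comet"), raw, tax))
  expect_false(compatible(getTool(model, "X! Tandem"), raw, tax))
  # every tool applies to its own declared input
  for (nm in toolNames(model)) {
    t <- getTool(model, nm)
    st <- DataState(t@input@data, t@input@formats[1L])
    expect_true(compatible(t, st, tax))
  }
})

test_that("successor states are exactly the applicable (tool, format) pairs", {
  model <- fixtureModel()
  succ <- successors(model, DataState("data:0943", "format:3712"))
  expect_setequal(unique(succ$tool), "msconvert")
  expect_identical(nrow(succ),
                   length(getTool(model, "msconvert")@output@formats))
  # deterministic total order
  expect_identical(succ, succ[order(succ$tool, succ$format), ])
  # every returned pair re-checks as compatible
  for (r in seq_len(nrow(succ)))
    expect_true(compatible(getTool(model, succ$tool[r]),
                           DataState("data:0943", "format:3712"),
                           model@taxonomy))
  # and successor states are declared outputs
  expect_true(all(succ$format %in%
                    getTool(model, "msconvert")@output@formats))

  none <- successors(model, DataState("data:1506", "format:3712"))
  expect_identical(nrow(none), 0L)
})

test_that("compatibility is monotone under added is-a edges", {
  for (seed in 1:10) {
    model <- randomDomain(randomDomainConfig(seed, nTools = 4L))
    tax <- model@taxonomy
    dataIds <- conceptIds(tax, "data")
    fmtIds <- conceptIds(tax, "format")
    states <- expand.grid(d = dataIds, f = fmtIds, stringsAsFactors = FALSE)
    before <- vapply(seq_len(nrow(states)), function(i)
      vapply(model@tools, compatible, logical(1),
             state = DataState(states$d[i], states$f[i]), taxonomy = tax),
      logical(length(model@tools)))
    # add one new is-a edge (format leaf under another format concept)
    set.seed(seed)
    leaf <- fmtIds[length(fmtIds)]
    tgt <- setdiff(fmtIds, descendants(tax, leaf))
    tgt <- setdiff(tgt, tax@ancestors[[leaf]])
    if (!length(tgt)) next
    df <- data.frame(id = tax@ids, label = tax@labels, branch = tax@branches,
                     parents = vapply(tax@parents[tax@ids], paste, "",
                                      collapse = "|"),
                     stringsAsFactors = FALSE)
    df$parents[df$id == leaf] <- paste(c(tax@parents[[leaf]], tgt[1L]),
                                       collapse = "|")
    tax2 <- try(Taxonomy(df), silent = TRUE)
    if (inherits(tax2, "try-error")) next   # edge would close a cycle
    after <- vapply(seq_len(nrow(states)), function(i)
      vapply(model@tools, compatible, logical(1),
             state = DataState(states$d[i], states$f[i]), taxonomy = tax2),
      logical(length(model@tools)))
    expect_true(all(after[before]))
  }
})

test_that("domain-model JSON round-trips", {
  model <- fixtureModel()
  f <- withr::local_tempfile(fileext = ".json")
  writeDomainModel(model, f)
  model2 <- loadDomainModel(f, model@taxonomy)
  expect_identical(toolNames(model2), toolNames(model))
  for (nm in toolNames(model)) {
    expect_identical(getTool(model2, nm)@input@formats,
                     getTool(model, nm)@input@formats)
    expect_identical(getTool(model2, nm)@output@formats,
                     getTool(model, nm)@output@formats)
  }
  expect_identical(vapply(globalConstraints(model2), formatConstraint, ""),
                   vapply(globalConstraints(model), formatConstraint, ""))
})
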