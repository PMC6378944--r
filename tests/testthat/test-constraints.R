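test_that("all five constraint templates parse, with curie, name and label fillers", {
  model <- fixtureModel()

  c1 <- parseConstraint("use operation:3633", model)
  expect_identical(c1@form, "USE")
  expect_identical(c1@atoms[[1L]]@ref, "operation:3633")

  # labels resolve when unambiguous (case-insensitive)
  c1b <- parseConstraint("use retention time prediction", model)
  expect_identical(c1b@atoms[[1L]]@ref, "operation:3633")

  c2 <- parseConstraint("do not use operation:3767", model)
  expect_identical(c2@form, "AVOID")

  c3 <- parseConstraint("use ProteinProphet only after PeptideProphet", model)
  expect_identical(c3@form, "ONLY_AFTER")
  expect_identical(vapply(c3@atoms, function(a) a@ref, ""),
                   c("ProteinProphet", "PeptideProphet"))
  expect_identical(vapply(c3@atoms, function(a) a@kind, ""),
                   c("tool", "tool"))

  c4 <- parseConstraint("do not use operation:3648 more than once", model)
  expect_identical(c4@form, "AT_MOST_ONCE")

  c5 <- parseConstraint("do not use msconvert directly after msconvert", model)
  expect_identical(c5@form, "NO_IMMEDIATE_REPEAT")

  # render-and-reparse is stable
  for (cn in list(c1, c2, c3, c4, c5))
    expect_identical(formatConstraint(parseConstraint(formatConstraint(cn),
                                                      model)),
                     formatConstraint(cn))
})

test_that("unparseable or unresolvable constraints fail loudly", {
  model <- fixtureModel()
  expect_error(parseConstraint("never ever use Comet", model),
               "unrecognised")
  expect_error(parseConstraint("use operation:9999", model), "operation:9999")
  expect_error(parseConstraint("use someUnknownTool", model),
               "someUnknownTool")
  expect_error(parseConstraint("use data:0943", model), "operation")
  expect_error(
    parseConstraint("do not use msconvert directly after idconvert", model),
    "same filler")
})

test_that("atoms match tools by name or by annotated operation subsumption", {
  model <- fixtureModel()
  tax <- model@taxonomy
  # Comet is annotated as peptide database search, a kind of peptide
  # identification
  expect_true(atomMatches(Atom("operation", "operation:3631"),
                          getTool(model, "Comet"), tax))
  expect_true(atomMatches(Atom("operation", "operation:3646"),
                          getTool(model, "Comet"), tax))
  expect_false(atomMatches(Atom("operation", "operation:3767"),
                           getTool(model, "SSRCalc"), tax))
  expect_true(atomMatches(Atom("tool", "msconvert"),
                          getTool(model, "msconvert"), tax))
  expect_false(atomMatches(Atom("tool", "msconvert"),
                           getTool(model, "Comet"), tax))
})

test_that("declarative trace semantics cover all forms and the empty trace", {
  model <- fixtureModel()
  pc <- function(s) parseConstraint(s, model)
  wf1 <- c("msconvert", "Comet", "PeptideProphet", "rt4")

  expect_true(evaluateTrace(pc("use operation:3633"), wf1, model))
  expect_false(evaluateTrace(pc("use operation:3767"), wf1, model))
  expect_true(evaluateTrace(pc("do not use operation:3767"), wf1, model))

  expect_false(evaluateTrace(
    pc("use ProteinProphet only after PeptideProphet"),
    c("msconvert", "Comet", "ProteinProphet"), model))
  expect_true(evaluateTrace(
    pc("use ProteinProphet only after PeptideProphet"),
    c("msconvert", "Comet", "PeptideProphet", "ProteinProphet"), model))

  expect_false(evaluateTrace(
    pc("do not use msconvert directly after msconvert"),
    c("msconvert", "msconvert"), model))
  expect_true(evaluateTrace(
    pc("do not use msconvert directly after msconvert"),
    c("msconvert", "Comet", "msconvert"), model))

  expect_false(evaluateTrace(
    pc("do not use operation:3648 more than once"),
    c("msconvert", "Comet", "PeptideProphet", "PeptideProphet"), model))

  # the empty trace satisfies everything except USE
  expect_false(evaluateTrace(pc("use Comet"), character(0), model))
  expect_true(evaluateTrace(pc("do not use Comet"), character(0), model))
  expect_true(evaluateTrace(pc("use Comet only after msconvert"),
                            character(0), model))
  expect_true(evaluateTrace(pc("do not use Comet more than once"),
                            character(0), model))
  expect_true(evaluateTrace(pc("do not use Comet directly after Comet"),
                            character(0), model))

  # a step matching A and B at once still violates "strictly preceded"
  selfAfter <- Constraint("ONLY_AFTER", list(Atom("tool", "Comet"),
                                             Atom("tool", "Comet")))
  expect_false(evaluateTrace(selfAfter, c("msconvert", "Comet"), model))

  expect_error(evaluateTrace(pc("use Comet"), c("nosuchtool"), model),
               "nosuchtool")
})

test_that("'only after' is vacuously true on traces without the target", {
  model <- fixtureModel()
  cn <- parseConstraint("use ProteinProphet only after PeptideProphet", model)
  expect_true(evaluateTrace(cn, c("msconvert", "Comet", "rt4"), model))
})

test_that("compiled monitors have the declared state counts and structure", {
  model <- fixtureModel()
  pc <- function(s) parseConstraint(s, model)
  sizes <- c("use Comet" = 2L, "do not use Comet" = 2L,
             "use Comet only after msconvert" = 3L,
             "do not use Comet more than once" = 3L,
             "do not use msconvert directly after msconvert" = 3L)
  for (s in names(sizes)) {
    mon <- compileMonitor(pc(s))
    expect_identical(mon@nStates, sizes[[s]])
    expect_true(validObject(mon))
  }
  useMon <- compileMonitor(pc("use Comet"))
  expect_false(useMon@accepting[useMon@initial])
  expect_true(runMonitor(useMon, c(1L, 2L, 1L)))   # flips permanently
  avoidMon <- compileMonitor(pc("do not use Comet"))
  expect_true(avoidMon@accepting[avoidMon@initial])
  expect_false(runMonitor(avoidMon, c(1L, 2L, 1L)))  # reject sink
  expect_true(any(avoidMon@sink))
})

test_that("monitor acceptance equals the declarative semantics on random traces", {
  model <- fixtureModel()
  tools <- toolNames(model)
  ops <- conceptIds(model@taxonomy, "operation")
  set.seed(424)
  for (rep in 1:40) {
    mkAtom <- function() {
      if (stats::runif(1) < 0.5) Atom("tool", sample(tools, 1L))
      else Atom("operation", sample(ops, 1L))
    }
    form <- sample(c("USE", "AVOID", "ONLY_AFTER", "AT_MOST_ONCE",
                     "NO_IMMEDIATE_REPEAT"), 1L)
    cn <- if (form == "ONLY_AFTER") Constraint(form, list(mkAtom(), mkAtom()))
          else Constraint(form, list(mkAtom()))
    mon <- compileMonitor(cn)
    for (k in 1:10) {
      trace <- sample(tools, sample(0:6, 1L), replace = TRUE)
      expect_identical(monitorAccepts(mon, trace, model),
                       evaluateTrace(cn, trace, model),
                       info = paste(formatConstraint(cn), "on",
                                    paste(trace, collapse = ",")))
    }
  }
})

test_that("adding a constraint never enlarges the satisfying trace set", {
  model <- fixtureModel()
  tools <- toolNames(model)
  pc <- function(s) parseConstraint(s, model)
  base <- list(pc("use operation:3631"))
  added <- c(base, list(pc("do not use Comet more than once")))
  ok <- function(cons, trace)
    all(vapply(cons, evaluateTrace, logical(1), trace = trace,
               model = model))
  set.seed(7)
  for (k in 1:100) {
    trace <- sample(tools, sample(0:5, 1L), replace = TRUE)
    if (ok(added, trace)) expect_true(ok(base, trace))
  }
})
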