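#' Bundled proteomics taxonomy excerpt
#'
#' Loads the packaged EDAM-style excerpt (operation, data, format and topic
#' concepts referenced by the bundled proteomics tools).
#'
#' @return a \linkS4class{Taxonomy}.
#' @export
proteomicsTaxonomy <- function() {
  path <- system.file("extdata", "edam_excerpt.tsv", package = "edamcompose",
                      mustWork = TRUE)
  loadTaxonomy(path, dialect = "table")
}

#' Bundled proteomics domain model
#'
#' The packaged model of shotgun-proteomics tools (msconvert, idconvert,
#' Comet, X! Tandem, Tandem2XML, PeptideProphet, iProphet, ProteinProphet,
#' PTMProphet, xml2tsv, SSRCalc, rt4, extract_protein_names, GeneTrail2,
#' EnrichNet, gProfileR, SearchGUI, PeptideShaker_VPSM, PeptideShaker_PTMI,
#' isobar, Libra) with the two global conversion constraints: msconvert and
#' idconvert must never run twice in a row, to prevent pointless chains of
#' format conversions.
#'
#' Per-tool format lists are a reconstruction; where the authoritative
#' annotation source was not available, lists were chosen to be realistic
#' for each tool and calibrated against published solution counts (see the
#' \code{notes} field of the JSON file and the package vignette).
#'
#' @return a \linkS4class{DomainModel}.
#' @export
proteomicsDomain <- function() {
  path <- system.file("extdata", "proteomics_tools.json",
                      package = "edamcompose", mustWork = TRUE)
  loadDomainModel(path, proteomicsTaxonomy())
}

#' Bundled use-case specifications
#'
#' The four shotgun-proteomics workflow specifications shipped with the
#' package.  All four start from mass-spectrometry spectra in Thermo RAW
#' format; the goals are (1) an amino acid index of hydropathy, via peptide
#' identification, PSM validation and retention-time prediction, avoiding
#' protein identification; (2) a pathway or network, via peptide
#' identification followed by gene-set enrichment analysis; (3) a protein
#' identification report with PTM identification after a single PSM
#' validation; (4) a gene expression profile via iTRAQ quantification after
#' PSM validation.
#'
#' @param useCase integer in 1..4.
#' @param model a \linkS4class{DomainModel} used to resolve constraint
#'   fillers; defaults to the bundled model.
#' @return a \linkS4class{WorkflowSpec}.
#' @export
useCaseSpec <- function(useCase, model = proteomicsDomain()) {
  if (!(length(useCase) == 1L && useCase %in% 1:4))
    stop("useCase must be a single integer in 1..4")
  path <- system.file("extdata", sprintf("usecase%d.json", useCase),
                      package = "edamcompose", mustWork = TRUE)
  loadWorkflowSpec(path, model)
}

#' Configuration for the random domain-model generator
#'
#' @param seed integer seed; generation is a pure function of the config.
#' @param nTools,nData,nFormats,nOperations component counts.
#' @param maxFormatsPerPort maximal formats per port.
#' @param depth depth of the random taxonomy trees.
#' @return a \linkS4class{RandomDomainConfig}.
#' @export
randomDomainConfig <- function(seed, nTools = 5L, nData = 3L, nFormats = 3L,
                               nOperations = 3L, maxFormatsPerPort = 2L,
                               depth = 2L) {
  obj <- new("RandomDomainConfig", seed = as.integer(seed),
             nTools = as.integer(nTools), nData = as.integer(nData),
             nFormats = as.integer(nFormats),
             nOperations = as.integer(nOperations),
             maxFormatsPerPort = as.integer(maxFormatsPerPort),
             depth = as.integer(depth))
  validObject(obj)
  obj
}

# run expr with a local RNG stream so generation never disturbs the
# caller's random state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded random domain model
#'
#' Builds a random tree taxonomy per branch and random single-port tools
#' whose concept references are type-correct by construction.  Identical
#' configurations yield identical models; useful for property tests.
#'
#' @param config a \linkS4class{RandomDomainConfig}.
#' @return a validated \linkS4class{DomainModel}.
#' @export
randomDomain <- function(config) {
  stopifnot(is(config, "RandomDomainConfig"))
  .withSeed(config@seed, {
    mkBranch <- function(branch, base, n, depth) {
      ids <- sprintf("%s:%d", branch, base + seq_len(n) - 1L)
      parents <- vector("list", n)
      parents[[1L]] <- character(0)            # root
      lvl <- integer(n); lvl[1L] <- 0L
      for (i in seq_len(n)[-1L]) {
        cand <- which(lvl[seq_len(i - 1L)] < depth)
        p <- if (length(cand) == 1L) cand else sample(cand, 1L)
        # occasionally a second parent: the taxonomy is a DAG, not a tree
        extra <- which(lvl[seq_len(i - 1L)] < depth)
        extra <- setdiff(extra, p)
        ps <- p
        if (length(extra) && stats::runif(1) < 0.15)
          ps <- c(p, if (length(extra) == 1L) extra else sample(extra, 1L))
        parents[[i]] <- ids[ps]
        lvl[i] <- max(lvl[ps]) + 1L
      }
      data.frame(id = ids,
                 label = paste0(branch, " concept ", seq_len(n)),
                 branch = branch,
                 parents = I(parents),
                 stringsAsFactors = FALSE)
    }
    tab <- rbind(
      mkBranch("operation", 9000L, config@nOperations, config@depth),
      mkBranch("data", 9000L, config@nData, config@depth),
      mkBranch("format", 9000L, config@nFormats, config@depth)
    )
    tax <- Taxonomy(tab)
    dataIds <- conceptIds(tax, "data")
    fmtIds <- conceptIds(tax, "format")
    opIds <- conceptIds(tax, "operation")
    pick <- function(x, n = 1L) if (length(x) == 1L) rep(x, n)[seq_len(n)]
                                else sample(x, n, replace = FALSE)
    tools <- lapply(seq_len(config@nTools), function(i) {
      nf <- sample(seq_len(min(config@maxFormatsPerPort, length(fmtIds))), 1L)
      ng <- sample(seq_len(min(config@maxFormatsPerPort, length(fmtIds))), 1L)
      ToolAnnotation(sprintf("tool%02d", i),
                     pick(opIds),
                     PortSpec(pick(dataIds), sort(pick(fmtIds, nf))),
                     PortSpec(pick(dataIds), sort(pick(fmtIds, ng))))
    })
    DomainModel(tax, tools, list(), edamVersion = "random")
  })
}
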