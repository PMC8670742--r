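#' Build a simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: a 500-contig community with 10% modified
#' contigs, negative-binomial counts (dispersion 0.3) at 50 control
#' reads/kb, a 10-fold case-coverage boost for modified contigs and a
#' 10-fold depletion for unmodified ones, 3 planted phenotype-associated
#' domain families at 0.9 prevalence on modified contigs versus 0.02
#' background, 50 background families, and a 20-rows-per-group, 100
#' column grouped alignment with one planted group-differential column
#' at 5% substitution noise.
#'
#' @param seed master seed; all generator randomness derives from it.
#' @param nContigs,fractionModified,lengthRange community shape.
#' @param meanCoverage expected control reads per kb of contig.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param countModel `"nb"` or `"poisson"`.
#' @param enrichmentFactor,depletionFactor case-coverage multipliers for
#'   modified / unmodified contigs.
#' @param nDomains,nPlantedDomains,plantedPrevalence,backgroundPrevalence
#'   domain planting scheme.
#' @param hitDuplicationRate probability a placed hit is duplicated on
#'   its contig.
#' @param msaRowsPerGroup,msaWidth,msaPlantedColumns,msaNoise,msaGapRate
#'   grouped-alignment generator shape.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nContigs = 500L,
                             fractionModified = 0.1,
                             lengthRange = c(1000L, 10000L),
                             meanCoverage = 50, dispersion = 0.3,
                             countModel = "nb", enrichmentFactor = 10,
                             depletionFactor = 0.1, nDomains = 50L,
                             nPlantedDomains = 3L,
                             plantedPrevalence = 0.9,
                             backgroundPrevalence = 0.02,
                             hitDuplicationRate = 0.1,
                             msaRowsPerGroup = 20L, msaWidth = 100L,
                             msaPlantedColumns = 1L, msaNoise = 0.05,
                             msaGapRate = 0.05) {
  methods::new("SimulationConfig", seed = as.integer(seed),
               nContigs = as.integer(nContigs),
               fractionModified = fractionModified,
               lengthRange = as.integer(lengthRange),
               meanCoverage = meanCoverage, dispersion = dispersion,
               countModel = countModel,
               enrichmentFactor = enrichmentFactor,
               depletionFactor = depletionFactor,
               nDomains = as.integer(nDomains),
               nPlantedDomains = as.integer(nPlantedDomains),
               plantedPrevalence = plantedPrevalence,
               backgroundPrevalence = backgroundPrevalence,
               hitDuplicationRate = hitDuplicationRate,
               msaRowsPerGroup = as.integer(msaRowsPerGroup),
               msaWidth = as.integer(msaWidth),
               msaPlantedColumns = as.integer(msaPlantedColumns),
               msaNoise = msaNoise, msaGapRate = msaGapRate)
}

# every stage seeds independently from the master seed so stages can be
# rerun in isolation and still reproduce the full-run output
.stageSeed <- function(config, offset) {
  set.seed((config@seed * 1000L + offset) %% .Machine$integer.max)
}

#' Simulate a contig community with known modification status
#'
#' Draws random nucleotide contigs in the configured length range and
#' assigns each a true modified/unmodified status at the configured
#' fraction. Truth lives in the returned table, never in the sequence
#' names, so downstream parsers cannot shortcut it.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `contigs` ([Biostrings::DNAStringSet]) and `truth`
#'   (`DataFrame` with `contig_id`, `true_status`).
#' @export
simulateCommunity <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  .stageSeed(config, 1L)
  n <- config@nContigs
  ids <- sprintf("CTG%05d", seq_len(n))
  lens <- sample(config@lengthRange[1]:config@lengthRange[2], n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- ids
  nMod <- round(n * config@fractionModified)
  status <- rep("unmodified", n)
  status[sample.int(n, nMod)] <- "modified"
  list(contigs = contigs,
       truth = S4Vectors::DataFrame(contig_id = ids, true_status = status))
}

#' Simulate case/control mapped-read counts
#'
#' Control counts follow the configured count distribution with mean
#' proportional to contig length (meanCoverage reads per kb); case
#' counts use the same distribution with the mean multiplied by the
#' enrichment factor on truly modified contigs and the depletion factor
#' on unmodified ones, emulating a selection that retains modified DNA
#' and washes out the rest. Setting both factors to 1 yields a null
#' dataset.
#'
#' @param config a [SimulationConfig-class].
#' @param community output of [simulateCommunity()].
#' @return a [CoverageTable-class].
#' @export
simulateCounts <- function(config, community) {
  stopifnot(methods::is(config, "SimulationConfig"))
  force(community)      # must not touch the RNG after the stage seed
  .stageSeed(config, 2L)
  truth <- community$truth
  lens <- Biostrings::width(community$contigs)[
    match(truth$contig_id, names(community$contigs))]
  mu_ctl <- config@meanCoverage * lens / 1000
  fac <- ifelse(truth$true_status == "modified",
                config@enrichmentFactor, config@depletionFactor)
  draw <- function(mu) {
    if (config@countModel == "poisson") stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / config@dispersion)
  }
  CoverageTable(S4Vectors::DataFrame(contig_id = truth$contig_id,
                                     length = as.integer(lens),
                                     count_control = draw(mu_ctl),
                                     count_case = draw(mu_ctl * fac)))
}

#' Simulate domain annotation with planted associated families
#'
#' Plants `nPlantedDomains` families on modified contigs at
#' `plantedPrevalence` and on unmodified contigs at
#' `backgroundPrevalence`, plus `nDomains` background families placed on
#' every contig at the background prevalence independently of status.
#' Every placement is given a fabricated ORF on the contig and
#' protein-relative hit coordinates within it; a configurable fraction
#' of hits is duplicated on its contig to exercise once-per-contig
#' counting. Accessions are sequential and carry no truth information;
#' the planted set is returned separately.
#'
#' @param config a [SimulationConfig-class].
#' @param community output of [simulateCommunity()].
#' @return list with `hits` (`DataFrame` in [readDomainHits()] layout),
#'   `orfs` (`GRanges`), and `planted` (character accessions of the
#'   planted families).
#' @export
simulateDomainHits <- function(config, community) {
  stopifnot(methods::is(config, "SimulationConfig"))
  force(community)      # must not touch the RNG after the stage seed
  .stageSeed(config, 3L)
  truth <- community$truth
  lens <- stats::setNames(Biostrings::width(community$contigs),
                          names(community$contigs))
  nFam <- config@nDomains + config@nPlantedDomains
  acc <- sprintf("PF%05d.%d", seq_len(nFam),
                 sample(1:30, nFam, replace = TRUE))
  planted <- sample(acc, config@nPlantedDomains)
  isMod <- truth$true_status == "modified"
  place <- list()
  for (am in acc) {
    prev <- if (am %in% planted)
      ifelse(isMod, config@plantedPrevalence, config@backgroundPrevalence)
    else rep(config@backgroundPrevalence, nrow(truth))
    on <- truth$contig_id[stats::runif(nrow(truth)) < prev]
    if (length(on)) place[[am]] <- on
  }
  if (length(place) == 0L)
    stop("no domain placed; raise prevalences or community size")
  df <- do.call(rbind, lapply(names(place), function(am)
    data.frame(accession = am, contig_id = place[[am]],
               stringsAsFactors = FALSE)))
  # duplicated hits on the same contig
  dup <- df[stats::runif(nrow(df)) < config@hitDuplicationRate, ,
            drop = FALSE]
  df <- rbind(df, dup)
  df <- df[order(df$contig_id, df$accession), , drop = FALSE]
  # one fabricated ORF per placement on its contig
  orfLen <- 900L
  cstart <- vapply(df$contig_id, function(cid)
    sample.int(max(1L, lens[[cid]] - orfLen), 1L), integer(1))
  orf_id <- sprintf("%s_orf%03d", df$contig_id,
                    stats::ave(seq_len(nrow(df)), df$contig_id,
                               FUN = seq_along))
  strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
  orfs <- GenomicRanges::GRanges(df$contig_id,
                                 IRanges::IRanges(cstart,
                                                  cstart + orfLen - 1L),
                                 strand = strand, orf_id = orf_id)
  protLen <- orfLen %/% 3L
  ali_start <- sample.int(protLen %/% 2L, nrow(df), replace = TRUE)
  ali_end <- pmin(protLen,
                  ali_start + sample(40:150, nrow(df), replace = TRUE))
  shortName <- sub("\\.[0-9]+$", "", df$accession)
  hits <- S4Vectors::DataFrame(
    contig_id = df$contig_id, orf_id = orf_id,
    pfam_accession = df$accession,
    pfam_name = paste0("dom_", shortName),
    i_evalue = 10^stats::runif(nrow(df), -30, -6),
    ali_start = as.integer(ali_start), ali_end = as.integer(ali_end),
    strand = strand)
  list(hits = hits, orfs = orfs, planted = sort(stripVersion(planted)))
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulate a group-labelled alignment with planted differential columns
#'
#' Background columns share one residue across all rows; planted columns
#' fix one residue for the modified group and a different one for the
#' unmodified group. Substitution noise (each cell independently
#' replaced by a random other residue at rate `msaNoise`) and gaps (at
#' rate `msaGapRate`) are then applied everywhere, the former degrading
#' within-group conservation, the latter exercising the occupancy
#' filter. The first modified-group row is the reference.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `alignment` (a [GroupedAlignment-class]),
#'   `plantedColumns` (integer indices) and `plantedResidues`
#'   (data.frame of the fixed residue pair per planted column).
#' @export
simulateGroupedAlignment <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  .stageSeed(config, 4L)
  nr <- 2L * config@msaRowsPerGroup
  w <- config@msaWidth
  m <- matrix(rep(sample(.AA20, w, replace = TRUE), each = nr), nr, w)
  planted <- sort(sample.int(w, config@msaPlantedColumns))
  isMod <- rep(c(TRUE, FALSE), each = config@msaRowsPerGroup)
  pr <- lapply(planted, function(j) {
    xy <- sample(.AA20, 2L)
    m[isMod, j] <<- xy[1L]
    m[!isMod, j] <<- xy[2L]
    data.frame(column = j, residue_modified = xy[1L],
               residue_unmodified = xy[2L], stringsAsFactors = FALSE)
  })
  # substitution noise
  flip <- matrix(stats::runif(nr * w) < config@msaNoise, nr, w)
  if (any(flip))
    m[flip] <- vapply(m[flip], function(a)
      sample(setdiff(.AA20, a), 1L), character(1))
  # gap injection
  gap <- matrix(stats::runif(nr * w) < config@msaGapRate, nr, w)
  m[gap] <- "-"
  ids <- c(sprintf("mod_%02d", seq_len(config@msaRowsPerGroup)),
           sprintf("unmod_%02d", seq_len(config@msaRowsPerGroup)))
  aln <- Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
  names(aln) <- ids
  labels <- stats::setNames(ifelse(isMod, "modified", "unmodified"), ids)
  ga <- GroupedAlignment(aln, labels, referenceId = ids[1L])
  list(alignment = ga, plantedColumns = planted,
       plantedResidues = do.call(rbind, pr))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits every fixture the pipeline consumes: contigs FASTA, counts TSV,
#' domtblout-layout hits, GFF3 ORFs, aligned FASTA with a labels TSV,
#' and truth side-car TSVs (contig status, planted domain accessions,
#' planted alignment columns). All files are plain text and round-trip
#' through the package readers.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
writeFixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  community <- simulateCommunity(config)
  coverage <- simulateCounts(config, community)
  ann <- simulateDomainHits(config, community)
  msa <- simulateGroupedAlignment(config)
  paths <- c(
    contigs = file.path(dir, "contigs.fasta"),
    counts = file.path(dir, "counts.tsv"),
    hits = file.path(dir, "hits.domtblout"),
    orfs = file.path(dir, "orfs.gff3"),
    alignment = file.path(dir, "alignment.fasta"),
    labels = file.path(dir, "alignment_labels.tsv"),
    truth_contigs = file.path(dir, "truth_contigs.tsv"),
    truth_domains = file.path(dir, "truth_domains.tsv"),
    truth_columns = file.path(dir, "truth_columns.tsv"))
  Biostrings::writeXStringSet(community$contigs, paths[["contigs"]])
  writeCountsTable(coverage, paths[["counts"]])
  orfLens <- stats::setNames(
    rep(300L, length(ann$orfs)), ann$orfs$orf_id)
  writeDomtblout(ann$hits, paths[["hits"]], orfLens)
  gr <- ann$orfs
  gr$ID <- gr$orf_id
  gr$type <- "gene"
  rtracklayer::export.gff3(gr, paths[["orfs"]])
  Biostrings::writeXStringSet(msa$alignment@aln, paths[["alignment"]])
  grp <- alignmentGroups(msa$alignment)
  utils::write.table(
    data.frame(sequence_id = names(grp), group = as.character(grp)),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(community$truth),
                     paths[["truth_contigs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(accession = ann$planted),
                     paths[["truth_domains"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(msa$plantedResidues, paths[["truth_columns"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
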