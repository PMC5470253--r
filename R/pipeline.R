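#' Assemble and validate a pipeline run configuration
#'
#' @param seed Integer seed; recorded in every output header and used (via
#'   fixed offsets) for every stage's RNG.
#' @param fixture Fixture name (see [build_fixture()]); the gene model,
#'   primers and editing metadata for the run.
#' @param outdir Output directory.
#' @param psi_clone,psi_parent True cassette-inclusion fractions used by
#'   the junction-read simulator for clone and parent.
#' @param depth Junction-read depth per sample.
#' @param read_length Read length (nt).
#' @param amplicon Optional list describing the editing spectrum at the
#'   cut site, e.g. `list(ins_fraction = 0.65, ins_seq = "T")`; the
#'   remainder is reference allele.
#' @param delta_min,reads_min,bf_min Event-calling thresholds.
#' @param sgrna_threshold Strong/weak guide threshold.
#' @param min_allele_freq Minimum reported indel-allele frequency.
#' @param stages Character vector of stages to run, in dependency order.
#' @return A validated `RunConfig` list.
#' @export
RunConfig <- function(seed = 1L, fixture = "kras", outdir = tempfile("run"),
                      psi_clone = 0.64, psi_parent = 1.0, depth = 5000L,
                      read_length = 75L,
                      amplicon = list(ins_fraction = 0.65, ins_seq = "T"),
                      delta_min = 0.2, reads_min = 10, bf_min = 10,
                      sgrna_threshold = 0.20, min_allele_freq = 0.005,
                      stages = c("simulate", "quantify", "events",
                                 "indels", "consequence")) {
  cfg <- list(seed = seed, fixture = fixture, outdir = outdir,
              psi_clone = psi_clone, psi_parent = psi_parent,
              depth = depth, read_length = read_length,
              amplicon = amplicon, delta_min = delta_min,
              reads_min = reads_min, bf_min = bf_min,
              sgrna_threshold = sgrna_threshold,
              min_allele_freq = min_allele_freq, stages = stages)
  validate_run_config(cfg)
}

#' @rdname RunConfig
#' @param config A config list (e.g. from [yaml::read_yaml()]); unknown
#'   fields are rejected, missing ones filled with defaults.
#' @export
validate_run_config <- function(config) {
  defaults <- formals(RunConfig)
  known <- names(defaults)
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("validation error: unknown config field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in known)
    if (is.null(config[[nm]])) config[[nm]] <- eval(defaults[[nm]])
  with(config, {
    if (!is.numeric(seed) || seed != as.integer(seed))
      stop("validation error: seed must be an integer")
    if (!fixture %in% fixture_names())
      stop("validation error: no such fixture: ", fixture)
    if (psi_clone < 0 || psi_clone > 1 || psi_parent < 0 || psi_parent > 1)
      stop("validation error: psi values must lie in [0,1]")
    if (depth <= 0) stop("validation error: depth must be positive")
    if (reads_min < 0) stop("validation error: reads_min must be >= 0")
    if (delta_min < 0 || delta_min > 1)
      stop("validation error: delta_min must lie in [0,1]")
    if (bf_min <= 0) stop("validation error: bf_min must be positive")
    if (sgrna_threshold < 0 || sgrna_threshold > 1)
      stop("validation error: sgrna_threshold must lie in [0,1]")
    if (min_allele_freq < 0 || min_allele_freq > 1)
      stop("validation error: min_allele_freq must lie in [0,1]")
  })
  structure(config, class = "RunConfig")
}

#' Run the exon-skipping analysis pipeline end to end
#'
#' Executes the requested stages in dependency order on one fixture:
#' simulate junction reads for clone and parent at their true PSI,
#' quantify junction counts and PSI, call the clone-vs-parent splicing
#' event, quantify the amplicon indel spectrum at the cut site, and report
#' transcript consequences (frame phase, RT-PCR band sizes, deletion
#' interpretation where the fixture carries a known lesion). Every table
#' is written with a '#'-prefixed provenance header (seed, package
#' version, thresholds) and a run manifest lists all artifacts. Identical
#' configurations produce byte-identical tables.
#'
#' @param config A `RunConfig` (or plain list passed through
#'   [validate_run_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of in-memory stage results plus `paths` of
#'   all written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- validate_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  prov <- c(sprintf("seed=%d", as.integer(cfg$seed)),
            sprintf("skipquant=%s",
                    as.character(utils::packageVersion("skipquant"))),
            sprintf("fixture=%s delta_min=%g reads_min=%g bf_min=%g",
                    cfg$fixture, cfg$delta_min, cfg$reads_min, cfg$bf_min))
  fx <- build_fixture(cfg$fixture)
  gm <- fx$model
  labs <- gm$exons$label
  cassette <- labs[1:3]  # first internal cassette of the fixture
  res <- list(config = cfg, paths = character())
  add_path <- function(p) res$paths <<- c(res$paths, p)

  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  if ("simulate" %in% cfg$stages) wrap("simulate", {
    say("simulate: junction reads (", cfg$fixture, ")")
    mk_mix <- function(psi) IsoformMixture(
      gm, list(cassette, cassette[c(1L, 3L)]), c(psi, 1 - psi))
    sc <- function(off) SimConfig(seed = as.integer(cfg$seed) + off,
                                  depth = cfg$depth,
                                  read_length = cfg$read_length)
    res$sim_clone <- simulate_junction_reads(mk_mix(cfg$psi_clone), sc(11L))
    res$sim_parent <- simulate_junction_reads(mk_mix(cfg$psi_parent), sc(12L))
    for (nm in c("sim_clone", "sim_parent")) {
      sam <- file.path(cfg$outdir, paste0(nm, ".sam"))
      write_sam(res[[nm]]$alignments, sam, res[[nm]]$seqlengths,
                comments = prov)
      add_path(sam)
      tt <- file.path(cfg$outdir, paste0(nm, "_truth.tsv"))
      write_tsv_prov(res[[nm]]$truth$junctions, tt, prov)
      add_path(tt)
    }
  })

  if ("quantify" %in% cfg$stages) wrap("quantify", {
    say("quantify: junction counts and PSI")
    res$counts_clone <- count_junction_reads(
      res$sim_clone$alignments, gm, sample_id = "clone")
    res$counts_parent <- count_junction_reads(
      res$sim_parent$alignments, gm, sample_id = "parent")
    jc <- rbind(as.data.frame(res$counts_clone),
                as.data.frame(res$counts_parent))
    p <- file.path(cfg$outdir, "junction_counts.tsv")
    write_tsv_prov(jc, p, prov); add_path(p)
    psi <- data.frame(
      sample = c("clone", "parent"),
      psi = c(compute_psi(res$counts_clone, cassette),
              compute_psi(res$counts_parent, cassette)))
    res$psi <- psi
    p <- file.path(cfg$outdir, "psi_report.tsv")
    write_tsv_prov(psi, p, prov); add_path(p)
  })

  if ("events" %in% cfg$stages) wrap("events", {
    say("events: clone-vs-parent splicing call")
    icc <- inclusion_counts(res$counts_clone, cassette)
    icp <- inclusion_counts(res$counts_parent, cassette)
    res$events <- call_events(
      clone = data.frame(gene = gm$gene_id, cassette = cassette[2L],
                         x = icc$x_inclusion, m = icc$m_total),
      parent = data.frame(gene = gm$gene_id, cassette = cassette[2L],
                          x = icp$x_inclusion, m = icp$m_total),
      delta_min = cfg$delta_min, reads_min = cfg$reads_min,
      bf_min = cfg$bf_min)
    p <- file.path(cfg$outdir, "events.tsv")
    write_tsv_prov(res$events, p, prov); add_path(p)
  })

  if ("indels" %in% cfg$stages && !is.null(cfg$amplicon)) wrap("indels", {
    say("indels: amplicon spectrum at the cut site")
    genome <- simulate_genome_sequence(gm, seed = as.integer(cfg$seed) + 13L)
    cass_row <- match(cassette[2L], gm$exons$label)
    cut_gen <- if (!is.null(fx$editing$sg1_cut)) fx$editing$sg1_cut$genomic
               else gm$exons$start[cass_row] +
                 (gm$exons$end[cass_row] - gm$exons$start[cass_row]) %/% 2L
    amp_start <- max(1L, cut_gen - 100L)
    amp_end <- min(nchar(genome), cut_gen + 100L)
    ref <- substr(genome, amp_start, amp_end)
    cut_local <- cut_gen - amp_start + 1L
    frac <- cfg$amplicon$ins_fraction
    spec <- IndelSpectrum("amplicon", cut_local, data.frame(
      type = c("ins", "ref"),
      sequence = c(cfg$amplicon$ins_seq, ""),
      length = c(nchar(cfg$amplicon$ins_seq), 0L),
      fraction = c(frac, 1 - frac)))
    sim <- simulate_amplicon_reads(
      spec, ref, SimConfig(seed = as.integer(cfg$seed) + 14L,
                           depth = cfg$depth, error_rate = 0.001))
    res$indels <- call_indels(sim$alignments, ref,
                              min_freq = cfg$min_allele_freq,
                              cut = cut_local)
    res$sgrna_class <- classify_sgrna(res$indels$edited_fraction,
                                      cfg$sgrna_threshold)
    p <- file.path(cfg$outdir, "indel_table.tsv")
    write_indel_table(res$indels, p,
                      c(prov, paste0("sgrna_class=", res$sgrna_class)))
    add_path(p)
  })

  if ("consequence" %in% cfg$stages) wrap("consequence", {
    say("consequence: frame phase and product sizes")
    fr <- frame_report(gm, cassette[2L])
    cons <- data.frame(
      item = c("skipped_exon", "skipped_length_nt", "in_frame"),
      value = c(cassette[2L], fr$skipped_length, fr$in_frame))
    if (!is.null(fx$primers)) {
      cons <- rbind(cons, data.frame(
        item = c("band_full_bp", "band_skip_bp"),
        value = c(predict_amplicon_size(gm, labs, fx$primers),
                  predict_amplicon_size(gm, setdiff(labs, cassette[2L]),
                                        fx$primers))))
    }
    del_meta <- fx$editing[grep("^deletion", names(fx$editing))]
    if (length(del_meta)) {
      bp <- del_meta[[1L]]
      da <- interpret_deletion(gm, bp["start"], bp["end"])
      res$deletion <- da
      cons <- rbind(cons, data.frame(
        item = c("deletion_bp", "deletion_removed_exons",
                 "deletion_transcript"),
        value = c(da$length, paste(da$removed_exons, collapse = ","),
                  da$predicted_transcript)))
    }
    res$consequence <- cons
    p <- file.path(cfg$outdir, "consequence.tsv")
    write_tsv_prov(cons, p, prov); add_path(p)
  })

  manifest <- file.path(cfg$outdir, "manifest.tsv")
  write_tsv_prov(data.frame(artifact = basename(res$paths)), manifest, prov)
  res$paths <- c(res$paths, manifest)
  say("done: ", length(res$paths), " artifact(s) in ", cfg$outdir)
  invisible(res)
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [RunConfig()] arguments.
#' @param overrides Named list of values overriding the file.
#' @return A validated `RunConfig`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_run_config(cfg)
}
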