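manifest_log <- function(manifest, msg) {
  manifest$log <- c(manifest$log,
                    paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg))
  manifest
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  md5 <- tools::md5sum(paths)
  stats::setNames(as.list(unname(md5)), basename(paths))
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a pipeline stage
#'
#' Orchestrates the package's modules as reproducible, manifest-logged
#' runs. Every stage writes its outputs plus a `run_manifest.json`
#' (config echo, seed, input digests, scale factors, operation log,
#' output list) into `out_dir`; the same config and seed reproduce
#' bit-identical outputs for the deterministic stages and identical
#' streams for the stochastic ones.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{Generate the full synthetic fixture set (gene/exon
#'     tables, DSB BED, bedGraph track pairs, DRB time-course matrices,
#'     `truth/` tables, config echo).}
#'   \item{classify}{Classify `dsbs.bed` against `genes.tsv`/`exons.tsv`
#'     in `in_dir` and write annotations plus category counts.}
#'   \item{strandsplit}{Split qDRIP +DSB/-DSB tracks around the breaks
#'     into overhang/resected windowed sums per site.}
#'   \item{normalize}{Compute and apply the TSS-metagene scale factor to
#'     the RNAPII +DSB track.}
#'   \item{profile}{Anchor-centred profile matrix of a named track
#'     around the breaks.}
#'   \item{quantify}{Windowed per-site signal table for a named track.}
#'   \item{elongation}{Wave-peak elongation rates from the simulated DRB
#'     time course.}
#'   \item{report}{Condense a run directory's tables into one JSON
#'     summary.}
#' }
#'
#' @param command One of the stage names above.
#' @param config A [simulation_config()], a YAML path, or `NULL` for
#'   defaults.
#' @param out_dir Output directory (created if needed).
#' @param in_dir Input directory for stages consuming a previous
#'   `simulate` run (defaults to `out_dir`).
#' @param seed Optional seed override.
#' @param track Track name for `profile`/`quantify`
#'   (default `"qdrip_plus"`).
#' @param halfwidth Window half-width in bp for
#'   `strandsplit`/`profile`/`quantify` (default 2000).
#' @return The stage's main result, invisibly for writing stages; the
#'   manifest path is attached as attribute `manifest`.
#' @export
run_pipeline <- function(command = c("simulate", "classify", "strandsplit",
                                     "normalize", "profile", "quantify",
                                     "elongation", "report"),
                         config = NULL, out_dir = ".", in_dir = out_dir,
                         seed = NULL, track = "qdrip_plus",
                         halfwidth = 2000) {
  command <- match.arg(command)
  if (is.character(config)) config <- config_from_yaml(config, seed = seed)
  if (is.null(config)) config <- simulation_config(seed = if (is.null(seed)) 1L else seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = command, seed = config$seed,
                   config = unclass(config), inputs = list(),
                   scale_factors = list(), outputs = character(0),
                   log = character(0))
  manifest <- manifest_log(manifest, paste("start", command))

  sim_paths <- function(dir) {
    list(genes = file.path(dir, "genes.tsv"),
         exons = file.path(dir, "exons.tsv"),
         dsbs = file.path(dir, "dsbs.bed"))
  }
  load_track <- function(dir, name) {
    load_stranded_track(file.path(dir, paste0(name, "_watson.bedGraph")),
                        file.path(dir, paste0(name, "_crick.bedGraph")),
                        config$chrom_sizes, config$bin_size)
  }

  result <- switch(command,
    simulate = {
      genome <- simulate_genome(config)
      dsbs <- simulate_dsbs(config, genome)
      bundle <- simulate_tracks(config, genome, dsbs)
      drb <- simulate_drb_timecourse(config)
      p <- sim_paths(out_dir)
      write_gene_table(genome$genes, p$genes)
      utils::write.table(genome$exons, p$exons, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_dsb_bed(dsbs, p$dsbs)
      outs <- c(p$genes, p$exons, p$dsbs)
      for (nm in names(bundle$tracks)) {
        outs <- c(outs, write_stranded_track(bundle$tracks[[nm]],
                                             file.path(out_dir, nm)))
      }
      for (i in seq_along(drb$timecourses)) {
        tc <- drb$timecourses[[i]]
        f <- file.path(out_dir, sprintf("drb_%s.tsv", tc$gene_id))
        m <- cbind(position = tc$positions, t(tc$coverage))
        colnames(m) <- c("position", paste0("t", tc$times))
        utils::write.table(m, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outs <- c(outs, f)
      }
      truth_dir <- file.path(out_dir, "truth")
      dir.create(truth_dir, showWarnings = FALSE)
      utils::write.table(bundle$truth$dsbs,
                         file.path(truth_dir, "dsbs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bundle$truth$genes,
                         file.path(truth_dir, "genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(drb$truth, file.path(truth_dir, "drb_rates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      yaml::write_yaml(unclass(config),
                       file.path(out_dir, "config_echo.yaml"))
      spk <- file.path(out_dir, "spike_reads.tsv")
      utils::write.table(
        data.frame(library = names(bundle$spike_reads),
                   reads = unname(bundle$spike_reads)),
        spk, sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- c(outs, file.path(truth_dir, c("dsbs.tsv", "genes.tsv",
                                             "drb_rates.tsv")),
                file.path(out_dir, "config_echo.yaml"), spk)
      manifest$outputs <- basename(unname(outs))
      list(genome = genome, dsbs = dsbs, bundle = bundle, drb = drb)
    },
    classify = {
      p <- sim_paths(in_dir)
      manifest$inputs <- file_digest(unlist(p))
      genes <- read_gene_table(p$genes)
      exons <- utils::read.delim(p$exons, stringsAsFactors = FALSE)
      dsbs <- read_dsb_bed(p$dsbs)
      ann <- classify_dsbs(dsbs, genes, exons,
                           chrom_sizes = config$chrom_sizes)
      counts <- summarize_categories(ann)
      write_annotations(ann, file.path(out_dir, "annotations.tsv"))
      jsonlite::write_json(counts, file.path(out_dir, "categories.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$outputs <- c("annotations.tsv", "categories.json")
      list(annotations = ann, counts = counts)
    },
    strandsplit = {
      p <- sim_paths(in_dir)
      manifest$inputs <- file_digest(unlist(p))
      dsbs <- read_dsb_bed(p$dsbs)
      plus <- load_track(in_dir, "qdrip_plus")
      minus <- load_track(in_dir, "qdrip_minus")
      tab <- do.call(rbind, lapply(seq_len(nrow(dsbs)), function(i) {
        sp_p <- split_by_resection_sites(plus, dsbs[i, , drop = FALSE],
                                         halfwidth)
        sp_m <- split_by_resection_sites(minus, dsbs[i, , drop = FALSE],
                                         halfwidth)
        data.frame(dsb_id = dsbs$dsb_id[i],
                   overhang_plus = sum(sp_p$overhang),
                   resected_plus = sum(sp_p$resected),
                   overhang_minus = sum(sp_m$overhang),
                   resected_minus = sum(sp_m$resected),
                   stringsAsFactors = FALSE)
      }))
      f <- file.path(out_dir, "strandsplit.tsv")
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$outputs <- basename(f)
      tab
    },
    normalize = {
      p <- sim_paths(in_dir)
      manifest$inputs <- file_digest(unlist(p))
      genes <- read_gene_table(p$genes)
      plus <- load_track(in_dir, "rnapii_plus")
      minus <- load_track(in_dir, "rnapii_minus")
      sf <- tss_scale_factor(metagene_matrix(plus, genes),
                             metagene_matrix(minus, genes))
      scaled <- apply_scale(plus, sf)
      outs <- write_stranded_track(scaled,
                                   file.path(out_dir, "rnapii_plus_scaled"))
      manifest$scale_factors <- list(tss_metagene = sf$value)
      manifest$outputs <- basename(unname(outs))
      sf
    },
    profile = {
      p <- sim_paths(in_dir)
      manifest$inputs <- file_digest(unlist(p))
      dsbs <- read_dsb_bed(p$dsbs)
      tr <- load_track(in_dir, track)
      pm <- profile_matrix(tr, dsbs, halfwidth)
      f <- file.path(out_dir, paste0("profile_", track, ".tsv"))
      utils::write.table(pm, f, sep = "\t", quote = FALSE,
                         col.names = FALSE)
      manifest$outputs <- basename(f)
      pm
    },
    quantify = {
      p <- sim_paths(in_dir)
      manifest$inputs <- file_digest(unlist(p))
      dsbs <- read_dsb_bed(p$dsbs)
      tr <- load_track(in_dir, track)
      ws <- window_signal(tr, dsbs, halfwidth)
      tab <- data.frame(dsb_id = names(ws), signal = unname(ws),
                        stringsAsFactors = FALSE)
      f <- file.path(out_dir, paste0("quantify_", track, ".tsv"))
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$outputs <- basename(f)
      tab
    },
    elongation = {
      drb <- simulate_drb_timecourse(config)
      res <- cohort_rate(drb$timecourses)
      f <- file.path(out_dir, "elongation_rates.tsv")
      utils::write.table(res$rates, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$outputs <- basename(f)
      manifest$summary <- res$summary
      res
    },
    report = {
      files <- list.files(in_dir, pattern = "\\.(tsv|json)$",
                          full.names = TRUE)
      manifest$inputs <- file_digest(files)
      summary <- list(n_files = length(files),
                      files = basename(files))
      jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE)
      manifest$outputs <- "report.json"
      summary
    }
  )
  manifest <- manifest_log(manifest, paste("done", command))
  mpath <- write_manifest(manifest, out_dir)
  attr(result, "manifest") <- mpath
  invisible(result)
}
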