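#' Pipeline configuration
#'
#' Bundles everything [run_all()] needs. Exactly one input source must be
#' given: a FASTA path (with a group-map path) or a [sim_config()].
#'
#' @param fasta path to an aligned FASTA file, or `NULL`.
#' @param groups path to the group-map TSV (required with `fasta`).
#' @param simulation a [sim_config()], or `NULL`.
#' @param clades clade labels to analyze; default all clades in the map.
#' @param pooled_pair optional length-2 vector of clade labels for a pooled
#'   Kt row.
#' @param deletion site-exclusion convention for the diversity stage.
#' @param epsilon median-joining relaxation parameter.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (re-seeds the simulator when `simulation` is
#'   given).
#' @param formats report format(s), subset of `c("tsv", "json")`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, groups = NULL, simulation = NULL,
                            clades = NULL, pooled_pair = NULL,
                            deletion = c("complete", "pairwise"),
                            epsilon = 0L, out_dir, seed = 1L,
                            formats = "tsv") {
  deletion <- match.arg(deletion)
  if (is.null(fasta) == is.null(simulation))
    ns_stop("neustonet_config",
            "exactly one of `fasta` and `simulation` must be given")
  if (!is.null(fasta) && is.null(groups))
    ns_stop("neustonet_config", "a group map is required with a FASTA input")
  if (!is.null(pooled_pair) && length(pooled_pair) != 2L)
    ns_stop("neustonet_config", "pooled_pair must name exactly two clades")
  if (!all(formats %in% c("tsv", "json")))
    ns_stop("neustonet_config", "formats must be among tsv, json")
  structure(list(fasta = fasta, groups = groups, simulation = simulation,
                 clades = clades, pooled_pair = pooled_pair,
                 deletion = deletion, epsilon = as.integer(epsilon),
                 out_dir = out_dir, seed = as.integer(seed),
                 formats = formats),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end: input (load or simulate), per-clade
#' diversity statistics, per-clade median-joining networks, the
#' base-composition heterogeneity screen, and the UVR motif analysis.
#' Stages after input are independent: a failure in one is recorded in the
#' manifest and aborts only that stage. The manifest — tool version, config
#' echo, per-stage status/outputs/warnings/timings and a checksum for every
#' emitted file — is always written to `manifest.json` in `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest, invisibly (a list of class `run_manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "neustonet",
    version = as.character(utils::packageVersion("neustonet")),
    config = config_echo(config),
    stages = list(), files = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch(list(ok = TRUE, value = fun()),
               error = function(e) list(ok = FALSE, error = conditionMessage(e))),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = if (res$ok) "ok" else "error",
      error = if (res$ok) NULL else res$error,
      warnings = as.list(warns),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    if (res$ok) res$value else NULL
  }
  emit <- function(df, stem) {
    for (fmt in config$formats) {
      p <- file.path(config$out_dir, paste0(stem, ".", fmt))
      write_report(df, p, format = fmt)
      manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
    }
  }

  input <- run_stage("input", function() {
    if (!is.null(config$simulation)) {
      cfg <- config$simulation
      cfg$seed <- config$seed
      sim <- simulate_dataset(cfg)
      fa <- file.path(config$out_dir, "simulated.fasta")
      gm <- file.path(config$out_dir, "simulated.groups.tsv")
      tr <- file.path(config$out_dir, "simulated.truth.json")
      write_fasta(sim$sequences, fa)
      write_group_map(sim$groups, gm)
      jsonlite::write_json(sim$truth, tr, digits = NA, auto_unbox = TRUE,
                           force = TRUE)
      for (p in c(fa, gm, tr))
        manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
      list(sequences = sim$sequences, groups = sim$groups)
    } else {
      seqs <- read_fasta(config$fasta, alignment = TRUE)
      for (p in c(config$fasta, config$groups))
        manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
      list(sequences = seqs, groups = read_group_map(config$groups, seqs))
    }
  })
  if (is.null(input)) {
    manifest$stages$diversity <- manifest$stages$networks <-
      manifest$stages$composition <- manifest$stages$motifs <-
      list(status = "aborted", error = "input stage failed",
           warnings = list(), seconds = 0)
    return(write_manifest(manifest, config$out_dir))
  }
  seqs <- input$sequences; groups <- input$groups
  clades <- if (is.null(config$clades)) unique(groups$clade) else config$clades

  run_stage("diversity", function() {
    div <- diversity_by_clade(seqs, groups, clades, deletion = config$deletion)
    if (!is.null(config$pooled_pair)) {
      a <- groups$id[groups$clade == config$pooled_pair[1L]]
      b <- groups$id[groups$clade == config$pooled_pair[2L]]
      kt <- pooled_mean_differences(seqs, a, b, deletion = config$deletion)
      pooled_tab <- collapse_haplotypes(seqs, c(a, b))
      div <- rbind(div, data.frame(
        clade = paste(config$pooled_pair, collapse = "+"),
        n = length(c(a, b)), h = nrow(pooled_tab$haplotypes),
        Hd = haplotype_diversity(pooled_tab), K = kt,
        pi = kt / pooled_tab$analyzed_sites,
        analyzed_sites = pooled_tab$analyzed_sites))
    }
    emit(div, "diversity")
    div
  })
  run_stage("networks", function() {
    paths <- character(0)
    for (cl in clades) {
      ids <- intersect(seq_ids(seqs), groups$id[groups$clade == cl])
      net <- median_joining(collapse_haplotypes(seqs, ids),
                            epsilon = config$epsilon)
      p <- file.path(config$out_dir, sprintf("network_%s.graphml", cl))
      write_network(net, p, format = "graphml")
      manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
      paths <- c(paths, p)
    }
    paths
  })
  run_stage("composition", function() {
    comp <- composition_chisq(seqs)
    emit(comp, "composition")
    comp
  })
  run_stage("motifs", function() {
    counts <- count_salient(dealign(seqs))
    emit(counts, "motif_counts")
    emit(summarize_by_group(counts, groups), "motif_summary")
    counts
  })
  write_manifest(manifest, config$out_dir)
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out
}

write_manifest <- function(manifest, out_dir) {
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, digits = NA, auto_unbox = TRUE,
                       force = TRUE, null = "null")
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("neustonet run manifest (v%s)\n", x$version))
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s (%ss)%s\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds,
                if (length(x$stages[[nm]]$warnings))
                  sprintf(" [%d warning(s)]", length(x$stages[[nm]]$warnings))
                else ""))
  cat(sprintf("  %d file(s) emitted\n", length(x$files)))
  invisible(x)
}
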