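#' Run the full minimal-marker workflow
#'
#' Orchestrates filter -> select -> validate -> fingerprint -> robustness on
#' one genotype matrix, writing machine-readable stage outputs (TSVs plus a
#' JSON run report) under an output directory. Reruns with the same config
#' and seed produce byte-identical outputs. Any stage error aborts with the
#' stage name and cause.
#'
#' @param config a named list:
#' \describe{
#'   \item{input}{either `list(path =, dialect =, marker_meta =)` for a
#'     delimited genotype file, `list(vcf =)` for a VCF, or
#'     `list(simulate = list(...))` with [simulate_panel()] arguments.}
#'   \item{filter}{optional: `min_call_rate`, `min_maf`, `acc_call_rate`,
#'     `max_het`, `drop_monomorphic` (logical). Omit to skip filtering.}
#'   \item{selection}{optional: `forced`, `excluded`, `max_markers`,
#'     `policy`.}
#'   \item{panel}{optional path to an existing panel file; when given,
#'     selection is skipped and the panel is validated instead
#'     (validate-only mode).}
#'   \item{group_by}{optional accession-metadata column for the per-group
#'     discrimination summary.}
#'   \item{robustness}{optional: `reps` (default 200), `k_values`. Omit with
#'     `robustness = FALSE` to skip.}
#'   \item{out_dir}{output directory, created if needed.}
#'   \item{seed}{integer seed recorded in every output and used for
#'     simulation stages.}
#' }
#' @return The run report (also written as `report.json`), invisibly: filter
#'   counts, panel, discrimination rates, robustness table, package version
#'   and seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  report <- list(package = "minmark",
                 version = as.character(utils::packageVersion("minmark")),
                 seed = seed)

  gm <- stage("input", {
    inp <- config$input
    if (is.null(inp)) stop("no input configured")
    if (!is.null(inp$simulate)) {
      args <- inp$simulate
      if (is.null(args$seed)) args$seed <- seed
      sim <- do.call(simulate_panel, args)
      sim$matrix
    } else if (!is.null(inp$vcf)) {
      import_vcf(inp$vcf)
    } else {
      dialect <- if (is.null(inp$dialect)) genotype_dialect() else inp$dialect
      read_genotype_matrix(inp$path, dialect, marker_meta = inp$marker_meta)
    }
  })
  report$input <- list(n_accessions = nrow(gm), n_markers = ncol(gm))

  if (!is.null(config$filter) && !identical(config$filter, FALSE)) {
    f <- config$filter
    gm <- stage("filter", {
      fm <- filter_markers(gm,
                           min_call_rate = f$min_call_rate %||% 0.95,
                           min_maf = f$min_maf %||% 0.05)
      fa <- filter_accessions(fm$matrix,
                              min_call_rate = f$acc_call_rate %||% 0.995,
                              max_het = f$max_het %||% 0.001)
      removed <- rbind(cbind(what = "marker", fm$report$removed),
                       cbind(what = "accession", fa$report$removed))
      g <- fa$matrix
      if (isTRUE(f$drop_monomorphic %||% TRUE)) {
        dm <- drop_monomorphic(g)
        removed <- rbind(removed, cbind(what = "marker", dm$report$removed))
        g <- dm$matrix
      }
      utils::write.table(removed, file.path(out_dir, "filter_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$filter <- list(markers_in = fm$report$n_in,
                             markers_out = ncol(g),
                             accessions_in = fa$report$n_in,
                             accessions_out = nrow(g),
                             removed = as.list(table(removed$reason)))
      g
    })
  }

  stage("stats", {
    st <- marker_summary(gm)
    st[-1L] <- lapply(st[-1L], round, digits = 6)
    utils::write.table(st, file.path(out_dir, "marker_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  sel <- config$selection %||% list()
  panel <- stage("select", {
    if (!is.null(config$panel)) {
      read_panel(config$panel)
    } else {
      select_minimal_markers(gm,
                             forced = sel$forced %||% character(0),
                             excluded = sel$excluded %||% character(0),
                             max_markers = sel$max_markers,
                             policy = sel$policy %||% "strict")
    }
  })
  policy <- sel$policy %||% (if (!is.na(panel$policy)) panel$policy else "strict")
  val <- stage("validate", validate_panel(gm, panel, policy = policy))
  stage("write-panel", {
    write_panel(panel, file.path(out_dir, "panel.tsv"))
    utils::write.table(val$per_marker, file.path(out_dir, "panel_steps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  report$panel <- list(markers = panel$markers,
                       size = length(panel$markers),
                       resolved_fraction = val$resolved_fraction,
                       unresolved_pairs = nrow(val$unresolved_pairs))

  ft <- stage("fingerprint", {
    f <- fingerprint_table(gm, panel, policy = policy)
    write_fingerprints(f, file.path(out_dir, "fingerprints.tsv"))
    utils::write.table(
      data.frame(accession = names(f$groups), group = f$groups),
      file.path(out_dir, "groups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })
  report$discrimination_rate = discrimination_rate(ft)

  if (!is.null(config$group_by)) {
    report$by_group <- stage("group-summary", {
      bg <- summarize_by_group(ft, config$group_by, include_overall = TRUE)
      utils::write.table(bg, file.path(out_dir, "group_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bg
    })
  }

  if (!identical(config$robustness, FALSE) && length(panel$markers) >= 2L) {
    rob <- stage("robustness", {
      r <- marker_failure_simulation(gm, panel,
                                     reps = config$robustness$reps %||% 200,
                                     seed = seed,
                                     k_values = config$robustness$k_values,
                                     policy = policy, keep_replicates = FALSE)
      utils::write.table(robustness_plot_table(r),
                         file.path(out_dir, "robustness.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      r
    })
    report$robustness <- robustness_plot_table(rob)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
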