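#' Build a validated pipeline run configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param n_per_group subjects per group for the synthetic preset.
#' @param blocks named vector: stimulus blocks per subject by group.
#' @param block_size trials per block.
#' @param band band-pass edges in Hz.
#' @param window_starts,window_ends,window_names sub-stage windows (ms).
#' @param k edge count of the analysed networks (study default 90).
#' @param k_sweep optional vector of thresholds for the whole-trial
#'   global-metric sweep (e.g. `seq(90, 180, 15)`).
#' @param n_rand surrogate ensemble size for small-worldness.
#' @param seed master seed; all simulation and surrogate randomness derives
#'   from it.
#' @param fs,duration_ms sampling rate and trial length of the synthetic
#'   data.
#' @param input_meta optional character vector of per-subject metadata
#'   files (see [read_epochs_dir()]); when given, real recordings are
#'   analysed instead of synthetic ones.
#' @param quick logical; shrink to a smoke-test size (2 subjects/group,
#'   1 block, 5 surrogates).
#' @param stats run the statistics stage.
#' @return named list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       n_per_group = 11,
                       blocks = c(control = 6, patient = 2),
                       block_size = 96,
                       band = c(13, 30),
                       window_starts = c(0, 300, 800),
                       window_ends = c(300, 800, 1200),
                       window_names = c("Beginning", "Middle", "End"),
                       k = 90,
                       k_sweep = NULL,
                       n_rand = 20,
                       seed = 1L,
                       fs = 1000,
                       duration_ms = 1200,
                       input_meta = NULL,
                       quick = FALSE,
                       stats = TRUE) {
  if (quick) {
    n_per_group <- 2
    blocks <- c(control = 1, patient = 1)
    n_rand <- 5
  }
  cfg <- list(out_dir = out_dir, n_per_group = n_per_group,
              blocks = blocks, block_size = block_size, band = band,
              window_starts = window_starts, window_ends = window_ends,
              window_names = window_names, k = k, k_sweep = k_sweep,
              n_rand = n_rand, seed = as.integer(seed), fs = fs,
              duration_ms = duration_ms, input_meta = input_meta,
              quick = quick, stats = stats)
  # validation
  sub_stage_windows(window_starts, window_ends, window_names)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("invalid band")
  if (k < 1) stop("k must be positive")
  structure(cfg, class = "run_config")
}

cfg_windows <- function(cfg)
  sub_stage_windows(cfg$window_starts, cfg$window_ends, cfg$window_names)

log_line <- function(dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS1"),
                 paste0(...))
  message(msg)
  cat(msg, "\n", file = file.path(dir, "run.log"), append = TRUE)
}

psi_file <- function(dir, subject, window, hand, angle)
  file.path(dir, "psi",
            sprintf("%s__%s__%s_%d.tsv", subject, window, hand, angle))

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' loading, per subject), correct-trial selection, beta band-pass,
#' analytic-signal phase extraction, sub-stage segmentation, per-trial PSI
#' matrices, averaging into the 12 stimulus-type matrices per sub-stage,
#' hemispheric summaries, top-k network construction with nodal/global
#' metrics and small-worldness, and (optionally) the group statistics.
#' Every intermediate is persisted as delimited text under `out_dir`;
#' identical configuration + seed reproduces identical tables.
#'
#' Stage structure mirrors the cache: `connectivity` writes the per-type
#' association matrices and PSI tables; `network` consumes only those
#' files; `stats` consumes only the metric tables. Any later stage can be
#' re-run from a populated directory via the `stages` argument.
#'
#' @param config a [run_config()].
#' @param stages character subset of
#'   `c("connectivity", "network", "stats", "report")`.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("connectivity", "network", "stats",
                                    "report")) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  dir.create(file.path(dir, "psi"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tables"), showWarnings = FALSE)
  dir.create(file.path(dir, "stats"), showWarnings = FALSE)
  write_run_config(config_flat(config), file.path(dir, "config.toml"))
  if ("connectivity" %in% stages) stage_connectivity(config, dir)
  if ("network" %in% stages) stage_network(config, dir)
  if ("stats" %in% stages && isTRUE(config$stats)) stage_stats(config, dir)
  if ("report" %in% stages) {
    txt <- report_run(dir, print = FALSE)
    writeLines(txt, file.path(dir, "report.txt"))
  }
  invisible(dir)
}

config_flat <- function(cfg) {
  flat <- list()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.null(v)) next
    if (!is.null(names(v)) && !is.list(v)) {
      for (k in names(v)) flat[[paste0(nm, ".", k)]] <- v[[k]]
    } else flat[[nm]] <- v
  }
  flat
}

# which subjects does this run have?
cfg_subjects <- function(cfg) {
  if (!is.null(cfg$input_meta)) {
    metas <- lapply(cfg$input_meta, read_tsv)
    data.frame(subject = vapply(metas, function(m) m$subject[1], ""),
               group = vapply(metas, function(m) m$group[1], ""),
               index = seq_along(metas),
               meta = cfg$input_meta, stringsAsFactors = FALSE)
  } else {
    data.frame(
      subject = c(sprintf("C%02d", seq_len(cfg$n_per_group)),
                  sprintf("P%02d", seq_len(cfg$n_per_group))),
      group = rep(c("control", "patient"), each = cfg$n_per_group),
      index = rep(seq_len(cfg$n_per_group), 2),
      meta = NA_character_, stringsAsFactors = FALSE)
  }
}

stage_connectivity <- function(cfg, dir) {
  windows <- cfg_windows(cfg)
  sweep <- !is.null(cfg$k_sweep)
  subjects <- cfg_subjects(cfg)
  spec <- cohort_spec(max(2, cfg$n_per_group), cfg$blocks, cfg$block_size,
                      cfg$seed)
  psi_rows <- list()
  for (s in seq_len(nrow(subjects))) {
    si <- subjects[s, ]
    t0 <- Sys.time()
    es <- if (!is.na(si$meta)) read_epochs_dir(si$meta)
          else generate_subject(
            spec,
            if (si$group == "control") control_coupling()
            else patient_coupling(),
            si$group, si$index, fs = cfg$fs,
            duration_ms = cfg$duration_ms)
    es <- select_correct(es)
    conn <- compute_subject_connectivity(es, windows, cfg$band,
                                         sweep_window = sweep)
    for (wname in names(conn$avg)) {
      avg <- conn$avg[[wname]]
      for (cell in names(avg)) {
        if (is.null(avg[[cell]])) next
        hand <- sub("_.*", "", cell)
        angle <- as.numeric(sub(".*_", "", cell))
        write_assoc_matrix(avg[[cell]],
                           psi_file(dir, si$subject, wname, hand, angle))
      }
    }
    psi_rows[[length(psi_rows) + 1]] <- conn$hemi
    log_line(dir, sprintf(
      "connectivity %s (%s): %d trials x %d ch x %d smp, %.1fs",
      si$subject, si$group, dim(es$data)[1], dim(es$data)[2],
      dim(es$data)[3], as.numeric(Sys.time() - t0, units = "secs")))
  }
  write_tsv(subjects[, c("subject", "group")],
            file.path(dir, "tables", "subjects.tsv"))
  write_tsv(do.call(rbind, psi_rows),
            file.path(dir, "tables", "psi_long.tsv"))
}

stage_network <- function(cfg, dir) {
  subjects <- read_tsv(file.path(dir, "tables", "subjects.tsv"))
  files <- list.files(file.path(dir, "psi"), pattern = "\\.tsv$")
  info <- do.call(rbind, lapply(files, function(f) {
    p <- strsplit(sub("\\.tsv$", "", f), "__")[[1]]
    ha <- strsplit(p[3], "_")[[1]]
    data.frame(file = f, subject = p[1], window = p[2], hand = ha[1],
               angle = as.numeric(ha[2]), stringsAsFactors = FALSE)
  }))
  glob <- list(); nodal <- list(); sweep_rows <- list()
  sub_stage_files <- info[info$window != "Whole", ]
  for (r in seq_len(nrow(sub_stage_files))) {
    fi <- sub_stage_files[r, ]
    M <- read_assoc_matrix(file.path(dir, "psi", fi$file))
    W <- threshold_topk(M, cfg$k)
    nm <- network_metrics(W, n_rand = cfg$n_rand,
                          seed = derive_seed(cfg$seed, 50000L + r, 0L))
    grp <- subjects$group[match(fi$subject, subjects$subject)]
    base <- data.frame(subject = fi$subject, group = grp,
                       substage = fi$window, hand = fi$hand,
                       angle = fi$angle, k = cfg$k,
                       stringsAsFactors = FALSE)
    glob[[length(glob) + 1]] <- cbind(
      base[rep(1, 4), ],
      data.frame(metric = c("C", "L", "sigma", "n_unreachable"),
                 value = c(nm$global_clustering, nm$char_path_length,
                           nm$sigma, nm$n_unreachable_pairs)))
    nodal[[length(nodal) + 1]] <- cbind(
      base[rep(1, 2 * length(nm$nodal_clustering)), ],
      data.frame(metric = rep(c("clustering", "betweenness"),
                              each = length(nm$nodal_clustering)),
                 channel = rep(names(nm$nodal_clustering), 2),
                 value = c(unname(nm$nodal_clustering),
                           unname(nm$nodal_betweenness))))
  }
  write_tsv(do.call(rbind, glob), file.path(dir, "tables",
                                            "global_long.tsv"))
  ntab <- do.call(rbind, nodal)
  rownames(ntab) <- NULL
  write_tsv(ntab, file.path(dir, "tables", "nodal_long.tsv"))
  if (!is.null(cfg$k_sweep)) {
    whole <- info[info$window == "Whole", ]
    for (subj in unique(whole$subject)) {
      fs <- whole$file[whole$subject == subj]
      M <- Reduce(`+`, lapply(fs, function(f)
        read_assoc_matrix(file.path(dir, "psi", f)))) / length(fs)
      grp <- subjects$group[match(subj, subjects$subject)]
      for (kk in cfg$k_sweep) {
        W <- threshold_topk(M, kk)
        nm <- network_metrics(W, n_rand = cfg$n_rand,
                              seed = derive_seed(cfg$seed, 60000L + kk,
                                                 match(subj,
                                                       subjects$subject)))
        sweep_rows[[length(sweep_rows) + 1]] <- data.frame(
          subject = subj, group = grp, k = kk,
          metric = c("C", "L", "sigma"),
          value = c(nm$global_clustering, nm$char_path_length, nm$sigma),
          stringsAsFactors = FALSE)
      }
    }
    write_tsv(do.call(rbind, sweep_rows),
              file.path(dir, "tables", "sweep_global.tsv"))
  }
  log_line(dir, sprintf("network: %d sub-stage networks at k = %d%s",
                        nrow(sub_stage_files), cfg$k,
                        if (is.null(cfg$k_sweep)) ""
                        else paste0(", sweep k = ",
                                    paste(cfg$k_sweep, collapse = ","))))
}

# drop subjects lacking any within-cell (rm-ANOVA needs complete cells);
# imputation would invent data, so exclusion is logged instead
drop_incomplete <- function(d, within, dir = NULL) {
  cell <- interaction(d[within], drop = FALSE)
  tab <- table(d$subject, cell)
  bad <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
  if (length(bad)) {
    if (!is.null(dir))
      log_line(dir, "stats: excluding subject(s) with incomplete cells: ",
               paste(bad, collapse = ", "))
    d <- d[!d$subject %in% bad, ]
  }
  d
}

stage_stats <- function(cfg, dir) {
  psi <- read_tsv(file.path(dir, "tables", "psi_long.tsv"))
  glob <- read_tsv(file.path(dir, "tables", "global_long.tsv"))
  for (ss in unique(psi$substage)) {
    d <- psi[psi$substage == ss, ]
    d <- drop_incomplete(d, c("hemisphere", "angle", "hand"), dir)
    a <- tryCatch(rm_anova(d, within = c("hemisphere", "angle", "hand")),
                  error = function(e) {
                    log_line(dir, "stats: PSI ANOVA failed in ", ss, ": ",
                             conditionMessage(e))
                    NULL
                  })
    if (!is.null(a))
      write_tsv(a, file.path(dir, "stats",
                             sprintf("anova_psi_%s.tsv", ss)))
  }
  for (metric in c("C", "L", "sigma")) {
    for (ss in unique(glob$substage)) {
      d <- glob[glob$substage == ss & glob$metric == metric, ]
      d <- drop_incomplete(d, c("angle", "hand"), dir)
      a <- tryCatch(rm_anova(d, within = c("angle", "hand")),
                    error = function(e) NULL)
      if (!is.null(a))
        write_tsv(a, file.path(dir, "stats",
                               sprintf("anova_%s_%s.tsv", metric, ss)))
    }
  }
  # channel-level group contrasts (mean over hand x angle), BH-FDR masks
  npath <- file.path(dir, "tables", "nodal_long.tsv")
  if (file.exists(npath)) {
    nodal <- read_tsv(npath)
    rows <- list()
    for (metric in unique(nodal$metric)) {
      for (ss in unique(nodal$substage)) {
        d <- nodal[nodal$metric == metric & nodal$substage == ss, ]
        agg <- stats::aggregate(value ~ subject + group + channel, d, mean)
        tt <- posthoc_t(agg, by = "channel")
        fdr <- fdr_bh(tt$p[!is.na(tt$p)], 0.05)
        tt$sig_unc <- !is.na(tt$p) & tt$p < 0.05
        tt$sig_fdr <- FALSE
        tt$sig_fdr[!is.na(tt$p)] <- fdr$reject
        tt$metric <- metric; tt$substage <- ss
        rows[[length(rows) + 1]] <- tt
      }
    }
    write_tsv(do.call(rbind, rows),
              file.path(dir, "stats", "posthoc_channels.tsv"))
  }
  spath <- file.path(dir, "tables", "sweep_global.tsv")
  if (file.exists(spath)) {
    sw <- read_tsv(spath)
    rows <- list()
    for (metric in unique(sw$metric)) {
      d <- sw[sw$metric == metric, ]
      tt <- posthoc_t(d, by = "k")
      fdr <- fdr_bh(tt$p, 0.05)
      tt$sig_fdr <- fdr$reject
      tt$metric <- metric
      rows[[length(rows) + 1]] <- tt
    }
    write_tsv(do.call(rbind, rows),
              file.path(dir, "stats", "posthoc_k.tsv"))
  }
  log_line(dir, "stats: ANOVA and post-hoc tables written")
}

#' Summarise a completed pipeline run
#'
#' Renders a plain-text summary: per-sub-stage hemispheric PSI group
#' means, global network metric group means, the ANOVA effects, and the
#' channel-level significance masks (a tabular stand-in for topographic
#' maps). Missing stages are noted, not errors.
#'
#' @param dir a run directory produced by [run_pipeline()].
#' @param print print the summary to the console (default `TRUE`).
#' @return character vector of report lines, invisibly when printed.
#' @export
report_run <- function(dir, print = TRUE) {
  tdir <- file.path(dir, "tables")
  if (!file.exists(file.path(tdir, "psi_long.tsv")))
    stop("not a completed run directory: ", dir)
  out <- c(sprintf("synchnet run report: %s", normalizePath(dir)), "")
  psi <- read_tsv(file.path(tdir, "psi_long.tsv"))
  gpath <- file.path(tdir, "global_long.tsv")
  glob <- if (file.exists(gpath)) read_tsv(gpath) else NULL
  for (ss in unique(psi$substage)) {
    out <- c(out, sprintf("== %s sub-stage ==", ss))
    d <- psi[psi$substage == ss, ]
    m <- stats::aggregate(value ~ group + hemisphere, d, mean)
    out <- c(out, "  mean PSI (group x hemisphere):")
    for (r in seq_len(nrow(m)))
      out <- c(out, sprintf("    %-8s %-6s %.4f", m$group[r],
                            m$hemisphere[r], m$value[r]))
    if (!is.null(glob)) {
      g <- glob[glob$substage == ss & glob$metric %in% c("C", "L", "sigma"), ]
      gm <- stats::aggregate(value ~ group + metric, g, mean)
      out <- c(out, sprintf("  global metrics at k = %d (group means):",
                            glob$k[1]))
      for (r in seq_len(nrow(gm)))
        out <- c(out, sprintf("    %-8s %-6s %.4f", gm$group[r],
                              gm$metric[r], gm$value[r]))
    }
    apath <- file.path(dir, "stats", sprintf("anova_psi_%s.tsv", ss))
    if (file.exists(apath)) {
      a <- read_tsv(apath)
      sig <- a[!is.na(a$p) & a$p < 0.05, ]
      out <- c(out, sprintf("  PSI ANOVA significant effects (p < 0.05):%s",
                            if (nrow(sig) == 0) " none" else ""))
      for (r in seq_len(nrow(sig)))
        out <- c(out, sprintf("    %-24s F(%d,%d) = %.3f, p = %.4g",
                              sig$effect[r], sig$df1[r], sig$df2[r],
                              sig$F[r], sig$p[r]))
    }
    out <- c(out, "")
  }
  if (!dir.exists(file.path(dir, "stats")) ||
      length(list.files(file.path(dir, "stats"))) == 0)
    out <- c(out, "statistics stage not run: stats skipped")
  ppath <- file.path(dir, "stats", "posthoc_channels.tsv")
  if (file.exists(ppath)) {
    pc <- read_tsv(ppath)
    sig <- pc[pc$sig_fdr, ]
    out <- c(out,
             sprintf("channel-level group differences (BH-FDR q<0.05): %d",
                     nrow(sig)))
    for (r in seq_len(min(nrow(sig), 30)))
      out <- c(out, sprintf("  %-12s %-10s %-6s p = %.4g", sig$metric[r],
                            sig$substage[r], sig$key[r], sig$p[r]))
  }
  if (print) {
    cat(paste(out, collapse = "\n"), "\n")
    return(invisible(out))
  }
  out
}
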