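#' Default pipeline configuration
#'
#' Returns the full configuration list used by [run_pipeline()], with every
#' stage parameter at its documented default. Override entries by passing a
#' partial list (or YAML file) to `run_pipeline()`; unknown keys are an
#' error so that typos in config files fail loudly.
#'
#' @return Nested named list of parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "tygcr_out",
    simulate = list(
      n_isolates = 8L,
      class_weights = c(I = 0.06, II = 0.60, III = 0.12, IV = 0.16, V = 0.06),
      sigma = 0.25,
      spacing_bp = 200L,
      base_intensity = 1000,
      background_frac = 0.05
    ),
    fluctuation = list(
      strains = list(
        list(strain = "WT", mu_plus = 8.4e-8, mu_minus = 2.2e-10),
        list(strain = "mutantX", mu_plus = 4.2e-6, mu_minus = 1.5e-9)
      ),
      n_cultures = 14L,
      n0 = 1000,
      n_t = 2e8
    ),
    segmentation = list(
      tau_log2 = 0.4, min_probes = 10L, min_gap = 3L, gap_bp = 2000L,
      merge_gap_bp = 10000L, frac_threshold = 0.3, spike_tolerance = 5L,
      tol_bp = 2000L
    ),
    classification = list(wt_kb = 624),
    junctions = list(n_chimeras = 4L, snp_rate = 1 / 150,
                     neither_run_cap = 3L)
  )
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    here <- c(path, nm)
    if (!nm %in% names(base)) {
      stopf("unknown configuration key: %s", paste(here, collapse = "$"))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Resolve a pipeline configuration
#'
#' Accepts NULL (all defaults), a partial named list, or a YAML file path,
#' and merges onto [default_pipeline_config()]. Unknown keys raise an error
#' naming the offending entry.
#'
#' @param config NULL, list, or YAML path.
#' @return Complete configuration list.
#' @export
resolve_pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("`config` must be NULL, a list, or a YAML path")
  cfg <- merge_config(base, config)
  w <- cfg$simulate$class_weights
  cfg$simulate$class_weights <- stats::setNames(as.numeric(w), names(w))
  cfg
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
             con)
  message(msg)
}

write_tsv_with_header <- function(df, path, config_md5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5: %s", config_md5), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study end to end on synthetic data: simulates
#' fluctuation assays and estimates rates with fold changes; simulates GCR
#' isolates, renders and segments their probe signal, classifies each event
#' and infers mechanisms with chromosome-size accounting; synthesizes
#' chimeric junctions and attributes their SNPs. All tabular outputs are
#' deterministic for a fixed `seed`: each TSV carries the MD5 of the
#' resolved configuration in a header comment, and timings go only to
#' `run.log` and the console, never into the tables.
#'
#' Outputs in `out_dir`: `config.yaml` (resolved configuration),
#' `rates.tsv`, `classes.tsv`, `sizes.tsv`, `junctions.tsv`, per-isolate
#' `isolates/<id>.json` (truth and call), and `run.log`.
#'
#' @param config NULL, partial list, or YAML path (see
#'   [resolve_pipeline_config()]).
#' @param genome Genome description: `list(map = chromosome_map-like
#'   data.frame, elements = repeat annotation)`. Defaults to the bundled
#'   reference genome.
#' @return Invisibly, a list with the resolved `config`, the output paths,
#'   and the in-memory `rates`, `classes`, `sizes`, `junctions` tables.
#' @export
run_pipeline <- function(config = NULL, genome = fixture_genome()) {
  cfg <- resolve_pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "isolates"), showWarnings = FALSE)
  log_con <- file(file.path(out, "run.log"), "w")
  on.exit(close(log_con))
  t0 <- Sys.time()

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  config_md5 <- unname(tools::md5sum(cfg_path))
  log_line(log_con, "pipeline start (seed %d, config md5 %s)",
           cfg$seed, config_md5)

  annotation <- repeat_annotation(genome$elements, genome$map)
  clusters <- cluster_elements(annotation)

  ## Stage 1: fluctuation assays and rates -------------------------------
  rates <- with_seed(cfg$seed, {
    fl <- cfg$fluctuation
    rows <- list()
    ests <- list()
    for (st in fl$strains) {
      for (assay in c("plusTy912", "minusTy")) {
        mu <- if (assay == "plusTy912") st$mu_plus else st$mu_minus
        counts <- simulate_fluctuation_cultures(mu, fl$n0, fl$n_t,
                                                fl$n_cultures)
        est <- estimate_rate_lc_median(
          fluctuation_experiment(counts, fl$n_t, strain = st$strain,
                                 assay = assay))
        ests[[paste(st$strain, assay, sep = ".")]] <- est
        rows[[length(rows) + 1L]] <- data.frame(
          strain = st$strain, assay = assay, true_rate = mu,
          median_count = est$median_count, rate = est$rate,
          ci_low = est$ci_low, ci_high = est$ci_high,
          censored = est$censored, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    wt <- ests[["WT.plusTy912"]]
    tab$fold_vs_wt_plus <- NA_character_
    if (!is.null(wt) && !wt$censored) {
      for (i in seq_len(nrow(tab))) {
        if (tab$assay[i] == "plusTy912") {
          key <- paste(tab$strain[i], "plusTy912", sep = ".")
          tab$fold_vs_wt_plus[i] <- fold_change(ests[[key]], wt)$label
        }
      }
    }
    tab
  })
  log_line(log_con, "rates: %d strain/assay estimates", nrow(rates))

  ## Stage 2: GCR isolates — simulate, segment, classify -----------------
  gcr <- with_seed(cfg$seed + 1L, {
    sm <- cfg$simulate
    sg <- cfg$segmentation
    classes_rows <- list(); sizes_rows <- list()
    event_classes <- sample(names(sm$class_weights), sm$n_isolates,
                            replace = TRUE, prob = sm$class_weights)
    for (i in seq_len(sm$n_isolates)) {
      id <- sprintf("S%02d", i)
      truth <- simulate_gcr_event(genome, event_class = event_classes[i])
      probes <- render_probe_signal(truth, genome, spacing_bp = sm$spacing_bp,
                                    sigma = sm$sigma,
                                    base_intensity = sm$base_intensity,
                                    background_frac = sm$background_frac)
      seg <- segment_isolate(probes, annotation, genome$map,
                             tau_log2 = sg$tau_log2,
                             min_probes = sg$min_probes,
                             min_gap = sg$min_gap, gap_bp = sg$gap_bp,
                             merge_gap_bp = sg$merge_gap_bp,
                             frac_threshold = sg$frac_threshold,
                             spike_tolerance = sg$spike_tolerance,
                             tol_bp = sg$tol_bp)
      call <- classify_gcr(seg$segments, seg$aneuploid_chroms, genome$map,
                           isolate = id)
      call <- infer_mechanism(call, genome$map,
                              wt_kb = cfg$classification$wt_kb)
      classes_rows[[i]] <- data.frame(
        isolate = id, true_class = truth$event_class,
        called_class = call$class_label, mechanism = call$mechanism,
        true_mechanism = truth$mechanism,
        n_duplications = nrow(call$amplified_segments),
        aneuploid = paste(call$aneuploid_chroms, collapse = ";"),
        stringsAsFactors = FALSE)
      amps <- call$amplified_segments
      del_kb <- if (is.null(call$chrV_deletion)) 0 else
        (call$chrV_deletion$end - call$chrV_deletion$start) / 1000
      dup_kb <- if (nrow(amps)) {
        (amps$end - amps$start) * pmax(amps$copy_number - 1, 1) / 1000
      } else numeric()
      sp <- predict_chromosome_size(del_kb, dup_kb,
                                    wt_kb = cfg$classification$wt_kb)
      sizes_rows[[i]] <- data.frame(
        isolate = id, deleted_kb = round(del_kb, 1),
        duplicated_kb = round(sum(dup_kb), 1),
        predicted_kb = sp$predicted_kb, stringsAsFactors = FALSE)
      iso <- list(isolate = id, truth = unclass_deep(truth),
                  call = unclass_deep(call),
                  size_prediction = unclass_deep(sp))
      jsonlite::write_json(iso, file.path(out, "isolates",
                                          paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null")
    }
    list(classes = do.call(rbind, classes_rows),
         sizes = do.call(rbind, sizes_rows))
  })
  log_line(log_con, "isolates: %d classified (%d class matches)",
           nrow(gcr$classes),
           sum(gcr$classes$true_class == gcr$classes$called_class))

  ## Stage 3: chimeric junctions -----------------------------------------
  junctions <- with_seed(cfg$seed + 2L, {
    jc <- cfg$junctions
    rows <- list()
    for (i in seq_len(jc$n_chimeras)) {
      pair <- simulate_ty_pair(snp_rate = jc$snp_rate)
      n_x <- sample(1:2, 1)
      xpos <- sort(sample(seq(200L, nchar(pair$seq_a) - 200L), n_x))
      jt <- synthesize_junction(pair, crossovers = xpos)
      att <- attribute_snps(jt$junction, pair$seq_a, pair$seq_b,
                            neither_run_cap = jc$neither_run_cap)
      rows[[i]] <- data.frame(
        chimera = sprintf("J%02d", i),
        true_crossovers = paste(xpos, collapse = ";"),
        n_crossovers = att$n_crossovers,
        intervals = paste(att$intervals$notation, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  log_line(log_con, "junctions: %d chimeras attributed", nrow(junctions))

  paths <- c(rates = file.path(out, "rates.tsv"),
             classes = file.path(out, "classes.tsv"),
             sizes = file.path(out, "sizes.tsv"),
             junctions = file.path(out, "junctions.tsv"))
  write_tsv_with_header(rates, paths["rates"], config_md5)
  write_tsv_with_header(gcr$classes, paths["classes"], config_md5)
  write_tsv_with_header(gcr$sizes, paths["sizes"], config_md5)
  write_tsv_with_header(junctions, paths["junctions"], config_md5)
  log_line(log_con, "pipeline done in %.1f s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(config = cfg, config_md5 = config_md5, paths = paths,
                 rates = rates, classes = gcr$classes, sizes = gcr$sizes,
                 junctions = junctions))
}

# Strip S3 classes recursively so jsonlite serializes plain structures.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
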