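# ---------------------------------------------------------------------------
# Config-driven pipeline runner. A pipeline is an ordered list of stages over
# the package's operations; each stage names its inputs (earlier stage
# results) and parameters. Reports embed the config hash and seed so reruns
# are verifiable; all randomized stages draw their seeds from the config seed
# via sub_seed(seed, stage_name).
# ---------------------------------------------------------------------------

PIPELINE_STAGE_TYPES <- c(
  "gen_curve", "gen_sec_frames", "reduce", "guinier", "pr", "dmax", "kratky",
  "mw", "gen_crosslinks", "quant", "map", "gen_variants", "filter_variants",
  "depletion", "gen_masses", "peaks", "stoichiometry", "footprint",
  "gen_beads", "beads")

validate_stage <- function(st, i) {
  if (is.null(st$name) || is.null(st$type))
    stop("stage ", i, " lacks 'name' or 'type'")
  if (!st$type %in% PIPELINE_STAGE_TYPES)
    stop("stage '", st$name, "': unknown type '", st$type, "'")
  known <- c("name", "type", "input", "params")
  extra <- setdiff(names(st), known)
  if (length(extra) > 0)
    stop("stage '", st$name, "': unknown key(s): ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Run a configured analysis pipeline
#'
#' The config (a YAML file or an equivalent list) has top-level keys `seed`
#' and `stages`; each stage is `list(name, type, input, params)` where `input`
#' names an earlier stage. Unknown keys are rejected before execution. The
#' returned report aggregates each stage's summary and embeds the config
#' hash, the seed and the package version; reruns with the same config and
#' seed produce an identical report.
#'
#' @param config path to a YAML file, or a list
#' @param out_path optional path for the JSON report
#' @return report list (invisibly written to `out_path` when given)
#' @export
run_pipeline <- function(config, out_path = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  top_known <- c("seed", "stages", "label")
  extra <- setdiff(names(config), top_known)
  if (length(extra) > 0)
    stop("unknown top-level config key(s): ", paste(extra, collapse = ", "))
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("config has an empty stage list")
  seed <- config$seed %||% 1
  for (i in seq_along(config$stages)) validate_stage(config$stages[[i]], i)
  nms <- vapply(config$stages, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate stage names")
  for (i in seq_along(config$stages)) {
    inp <- config$stages[[i]]$input
    if (!is.null(inp) && !inp %in% nms[seq_len(i - 1)])
      stop("stage '", nms[i], "' references unknown input '", inp, "'")
  }
  state <- list()
  summaries <- list()
  warn_log <- character(0)
  for (st in config$stages) {
    p <- st$params %||% list()
    s_seed <- sub_seed(seed, st$name)
    inp <- if (!is.null(st$input)) state[[st$input]] else NULL
    message(sprintf("[%s] stage %s (%s)",
                    format(Sys.time(), "%H:%M:%S"), st$name, st$type))
    res <- withCallingHandlers(
      run_stage(st$type, p, inp, s_seed),
      warning = function(w) {
        warn_log <<- c(warn_log, paste0(st$name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    state[[st$name]] <- res$value
    summaries[[st$name]] <- res$summary
  }
  cfg_file <- tempfile()
  yaml::write_yaml(config, cfg_file)
  report <- list(tool = "saxlink",
                 version = as.character(utils::packageVersion("saxlink")),
                 seed = seed,
                 config_hash = unname(tools::md5sum(cfg_file)),
                 warnings = warn_log,
                 stages = summaries)
  unlink(cfg_file)
  if (!is.null(out_path))
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(report)
}

run_stage <- function(type, p, inp, seed) {
  switch(type,
    gen_curve = {
      shape_params <- p[setdiff(names(p), c("shape", "noise_rel"))]
      if (length(shape_params) == 0) shape_params <- list(R = 50)
      g <- gen_curve(p$shape %||% "sphere", shape_params,
                     noise_rel = p$noise_rel %||% 0.01, seed = seed)
      list(value = g,
           summary = list(shape = g$truth$shape, truth_rg = g$truth$Rg,
                          truth_dmax = g$truth$dmax))
    },
    gen_sec_frames = {
      g <- gen_sec_frames(p$shape %||% "sphere",
                          list(R = p$R %||% 50), seed = seed)
      list(value = g, summary = list(n_frames = length(g$frames)))
    },
    reduce = {
      cur <- reduce_sec_frames(inp$frames, inp$buffer_ids, inp$sample_ids)
      list(value = list(curve = cur, truth = inp$truth),
           summary = list(n_points = nrow(cur)))
    },
    guinier = {
      g <- guinier_fit(inp$curve, qRg_limit = p$qRg_limit %||% 1.3)
      list(value = c(inp, list(guinier = g)),
           summary = g[c("status", "Rg", "I0", "npts")])
    },
    pr = {
      pr <- pr_ift(inp$curve, p$dmax, alpha = p$alpha)
      list(value = c(inp, list(pr = pr)),
           summary = list(dmax = pr$dmax, alpha = pr$alpha, chi2 = pr$chi2))
    },
    dmax = {
      grid <- seq(p$from, p$to, by = p$by %||% 5)
      est <- estimate_dmax(inp$curve, grid, alpha = p$alpha %||% 1e-4)
      list(value = c(inp, list(dmax_fit = est)),
           summary = list(status = est$status, dmax = est$dmax,
                          truth_dmax = inp$truth$dmax))
    },
    kratky = {
      k <- dimensionless_kratky(inp$curve, inp$guinier$Rg, inp$guinier$I0)
      pk <- which.max(k$y)
      list(value = c(inp, list(kratky = k)),
           summary = list(peak_x = k$x[pk], peak_y = k$y[pk]))
    },
    mw = {
      m <- mw_from_curve(inp$curve, inp$guinier,
                         species = p$species %||% "protein")
      list(value = c(inp, list(mw = m)),
           summary = m[c("mw_kda", "vc", "qr", "method")])
    },
    gen_crosslinks = {
      model <- make_fixture_structure(p$fixture %||% "cloud",
                                      n_res = p$n_res %||% 60,
                                      radius = p$radius %||% 30, seed = seed)
      g <- gen_crosslink_table(model, n_true = p$n_true %||% 10,
                               n_decoy = p$n_decoy %||% 10,
                               planted_fc = unlist(p$planted_fc) %||% 1,
                               cv = p$cv %||% 0.2, seed = seed)
      g$model <- model
      list(value = g, summary = list(n_features = nrow(g$features)))
    },
    quant = {
      cls <- classify_quant(inp$features,
                            conditions = unlist(p$conditions) %||%
                              c("control", "rna"),
                            fold_threshold = p$fold_threshold %||% 2)
      list(value = c(inp, list(classified = cls)),
           summary = as.list(table(cls$category)))
    },
    map = {
      rep_ <- map_distance(inp$features, inp$model,
                           chain_map = list(P1 = unique(
                             inp$model$atoms$chain)),
                           use_symmetry = p$use_symmetry %||% TRUE,
                           cutoff = p$cutoff %||% 24)
      list(value = c(inp, list(distances = rep_)),
           summary = list(satisfied = sum(rep_$satisfied, na.rm = TRUE),
                          total = sum(!is.na(rep_$satisfied))))
    },
    gen_variants = {
      doms <- if (!is.null(p$domains))
        do.call(rbind, lapply(p$domains, as.data.frame)) else NULL
      g <- gen_variant_track(p$protein_length %||% 500, doms,
                             baseline_rate = p$baseline_rate %||% 0.2,
                             seed = seed)
      g$domains <- doms
      list(value = g, summary = list(n_variants = nrow(g$variants)))
    },
    filter_variants = {
      fv <- filter_variants(inp$variants,
                            exclude = unlist(p$exclude) %||%
                              c("pathogenic", "clinvar"))
      out <- inp
      out$variants <- fv
      list(value = out,
           summary = list(retained = nrow(fv),
                          removed = as.list(attr(fv, "removed"))))
    },
    depletion = {
      dr <- depletion_ratio(inp$variants, c(p$start, p$end),
                            p$protein_length)
      list(value = c(inp, list(depletion = dr)),
           summary = dr[c("ratio", "v_d", "v_p", "status")])
    },
    gen_masses = {
      stoich <- do.call(rbind, lapply(p$stoich, as.data.frame))
      g <- gen_mass_events(stoich, p$m_protein, p$m_rna,
                           sigma = p$sigma %||% 8, n = p$n %||% 2000,
                           seed = seed)
      g$m_protein <- p$m_protein; g$m_rna <- p$m_rna
      list(value = g, summary = list(n_events = length(g$events)))
    },
    peaks = {
      pk <- fit_mass_peaks(inp$events, n_peaks = p$n_peaks %||% "auto")
      list(value = c(inp, list(peaks = pk)),
           summary = list(n_peaks = nrow(pk), masses = pk$mass))
    },
    stoichiometry = {
      asg <- assign_stoichiometry(inp$peaks, inp$m_protein, inp$m_rna,
                                  max_copies = p$max_copies %||% 10,
                                  tolerance = p$tolerance %||% 10)
      list(value = c(inp, list(assignments = asg)),
           summary = list(assigned = sum(asg$assigned),
                          compositions = paste0("(", asg$n_protein, ",",
                                                asg$n_rna, ")")))
    },
    footprint = {
      obs <- do.call(rbind, lapply(p$observations, function(o)
        data.frame(length_bp = o[[1]], max_pairs = o[[2]])))
      fp <- footprint_interval(obs)
      list(value = fp,
           summary = fp[c("lower", "upper", "empty")])
    },
    gen_beads = {
      g <- gen_bead_strings(n_strings = p$n_strings %||% 50,
                            spacing_mean = p$spacing_mean %||% 165,
                            seed = seed)
      list(value = g, summary = list(n_beads = nrow(g$measurements)))
    },
    beads = {
      bs <- bead_string_stats(inp$measurements)
      list(value = c(inp, list(stats = bs)),
           summary = list(spacing_mean = bs$spacing$mean,
                          width_mean = bs$width$mean,
                          n_gaps = bs$spacing$n))
    },
    stop("unhandled stage type: ", type))
}
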