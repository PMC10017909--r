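#' Plan a pressure x cosolvent simulation grid
#'
#' Enumerates the (parallel, pressure, ethanol fraction) runs of a
#' condition grid and the total simulated time. The reference study design
#' is 5 parallels x 3 pressures x 3 ethanol concentrations x 30 ns
#' = 45 runs, 1350 ns.
#'
#' @param parallels number of independent replicas per condition (>= 1).
#' @param pressures pressures in bar (non-empty).
#' @param ethanol_fractions ethanol volume fractions in `[0, 1]`
#'   (non-empty).
#' @param run_length_ns length of each run, ns.
#' @return A list of class `"run_plan"` with `runs` (data.frame of
#'   `parallel`, `pressure`, `ethanol_fraction` in deterministic order),
#'   `n_runs` and `total_ns`.
#' @export
plan_grid <- function(parallels, pressures, ethanol_fractions,
                      run_length_ns) {
  if (length(pressures) == 0 || length(ethanol_fractions) == 0) {
    stop("pressures and ethanol_fractions must be non-empty")
  }
  stopifnot(parallels >= 1, run_length_ns > 0)
  runs <- expand.grid(ethanol_fraction = ethanol_fractions,
                      pressure = pressures,
                      parallel = seq_len(parallels))[, 3:1]
  rownames(runs) <- NULL
  structure(list(runs = runs,
                 n_runs = nrow(runs),
                 total_ns = nrow(runs) * run_length_ns,
                 run_length_ns = run_length_ns),
            class = "run_plan")
}

#' @export
print.run_plan <- function(x, ...) {
  cat(sprintf("run plan: %d runs x %g ns = %g ns total\n",
              x$n_runs, x$run_length_ns, x$total_ns))
  invisible(x)
}

#' Default screening configuration
#'
#' The self-contained synthetic setup: the toy hydrolase fixture, the
#' reference condition grid (1/500/1000 bar x 10/50/100 % v/v ethanol,
#' 313 K, 5 parallels, 30 ns at 1-ns sampling), per-loop compressibility
#' targets in which three loops respond strongly to the conditions, and
#' the surrogate scorer.
#'
#' @param seed master seed for all generated data.
#' @return A config list accepted by [run_screen()].
#' @export
default_screen_config <- function(seed = 1) {
  loops <- c("loop_67-76", "loop_82-107", "loop_176-181", "loop_254-261",
             "loop_320-333", "loop_381-392")
  # bar^-1: sensitive loops get a large spread across conditions
  spread <- c(9e-6, 1e-6, 7e-6, 2e-6, 8e-6, 1e-6)
  names(spread) <- loops
  list(
    seed = seed,
    grid = list(parallels = 5, pressures = c(1, 500, 1000),
                ethanol_fractions = c(0.1, 0.5, 1.0),
                run_length_ns = 30, temperature = 313),
    regions = list(layout = "toy-hydrolase",
                   base_beta_t = 5e-6, spread = spread,
                   mean_volume = 1500),
    screen = list(top_k = 3, scorer = "surrogate", ddg_table = NULL),
    sampling = list(interval_ns = 1)
  )
}

.validate_screen_config <- function(config) {
  for (key in c("grid", "regions", "screen")) {
    if (is.null(config[[key]])) stop("config error: missing [", key, "] block")
  }
  g <- config$grid
  if (length(g$pressures) == 0 || length(g$ethanol_fractions) == 0) {
    stop("config error: empty condition grid")
  }
  sc <- config$screen
  if (is.null(sc$ddg_table) &&
      !identical(sc$scorer, "surrogate")) {
    stop("config error: no ddg_table and the surrogate scorer is disabled")
  }
  if (!is.null(sc$ddg_table) && !file.exists(sc$ddg_table)) {
    stop("config error: ddg_table not found: ", sc$ddg_table)
  }
  invisible(config)
}

#' Read a screening configuration from YAML
#'
#' @param path YAML file; its keys override [default_screen_config()].
#' @return Validated config list.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_screen_config(), user)
  .validate_screen_config(config)
}

# deterministic per-(region, condition) beta_T target: sensitive regions
# drift across the condition grid, insensitive ones stay flat
.series_target <- function(base, spread, cond_index, n_cond) {
  base + spread * (cond_index - 1) / max(1, n_cond - 1)
}

#' Run the end-to-end mutant screen
#'
#' Orchestrates the pipeline: condition grid -> per-region volume series ->
#' compressibility -> sensitivity ranking -> saturation enumeration ->
#' dual-predictor consensus filter. With the default synthetic config the
#' run is fully self-contained; supplying `screen$ddg_table` swaps the
#' surrogate scorer for external predictor exports. Writes TSV/JSON stage
#' outputs plus a manifest to `out_dir`; reruns on identical inputs are
#' byte-identical.
#'
#' @param config list from [default_screen_config()] /
#'   [read_screen_config()], or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `plan`, `grid`, `ranking`,
#'   `top_regions`, `candidates`, `filtered`, `stabilizing`, `paths`.
#' @export
run_screen <- function(config = default_screen_config(), out_dir = tempfile("screen_")) {
  if (is.character(config)) config <- read_screen_config(config)
  config <- .validate_screen_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- config$grid
  stage <- "plan"
  res <- tryCatch({
    plan <- plan_grid(g$parallels, g$pressures, g$ethanol_fractions,
                      g$run_length_ns)
    stage <- "regions"
    if (!identical(config$regions$layout, "toy-hydrolase")) {
      stop("unknown region layout: ", config$regions$layout)
    }
    layout <- toy_hydrolase_layout()
    ends <- cumsum(layout$length)
    partition <- region_partition(data.frame(class = layout$class,
                                             start = c(1, utils::head(ends, -1) + 1),
                                             end = ends))
    loops <- partition$name[partition$class == "loop"]
    sequence <- toy_hydrolase_sequence()

    stage <- "beta_t"
    conds <- unique(plan$runs[, c("pressure", "ethanol_fraction")])
    n_samp <- max(2, floor(g$run_length_ns / config$sampling$interval_ns))
    series <- list()
    for (j in seq_len(nrow(conds))) {
      cond <- condition(conds$pressure[j], conds$ethanol_fraction[j],
                        g$temperature)
      for (r in seq_along(loops)) {
        target <- .series_target(config$regions$base_beta_t,
                                 config$regions$spread[[loops[r]]],
                                 j, nrow(conds))
        series[[length(series) + 1]] <- generate_volume_series(
          target, config$regions$mean_volume, n = n_samp * g$parallels,
          temperature = g$temperature,
          seed = (config$seed * 1009 + j * 97 + r) %% 2147483647,
          dt = config$sampling$interval_ns, region_name = loops[r],
          condition = cond)
      }
    }
    grid <- beta_t_grid(series)

    stage <- "ranking"
    ranking <- sensitivity_ranking(grid)
    top <- top_regions(ranking, config$screen$top_k)

    stage <- "enumerate"
    top_rows <- partition[partition$name %in% top, ]
    candidates <- enumerate_saturation(sequence, top_rows)

    stage <- "score"
    scored <- if (!is.null(config$screen$ddg_table)) {
      attach_scores(candidates,
                    read_ddg_table(config$screen$ddg_table, sequence))
    } else {
      score_candidates(candidates, sequence, seed = config$seed)
    }

    stage <- "consensus"
    filtered <- consensus_filter(scored)
    stab <- stabilizing_subset(filtered)

    stage <- "write"
    paths <- list(
      grid = file.path(out_dir, "beta_t_grid.tsv"),
      ranking = file.path(out_dir, "ranking.tsv"),
      candidates = file.path(out_dir, "candidates.tsv"),
      stabilizing = file.path(out_dir, "stabilizing.tsv"),
      heatmap = file.path(out_dir, "heatmap.json"),
      manifest = file.path(out_dir, "manifest.json"))
    wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE)
    wt(grid, paths$grid)
    wt(as.data.frame(ranking), paths$ranking)
    wt(filtered, paths$candidates)
    wt(filtered[filtered$verdict == "stabilizing", ], paths$stabilizing)
    heatmap_to_json(heatmap_matrix(filtered), paths$heatmap)
    manifest <- list(
      package = "dhpmd",
      version = as.character(utils::packageVersion("dhpmd")),
      seed = config$seed,
      grid = config$grid,
      top_k = config$screen$top_k,
      scorer = if (is.null(config$screen$ddg_table)) "surrogate"
               else config$screen$ddg_table,
      n_runs = plan$n_runs, total_ns = plan$total_ns,
      top_regions = top, n_candidates = nrow(candidates),
      n_stabilizing = length(stab))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(plan = plan, grid = grid, ranking = ranking, top_regions = top,
         candidates = candidates, filtered = filtered, stabilizing = stab,
         paths = paths)
  }, error = function(e) {
    stop("screen failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
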