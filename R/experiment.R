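#' Configure a rewiring experiment
#'
#' An experiment crosses degree sequences with configuration-model
#' replicate networks, run repetitions and rewiring algorithms. The
#' reference design is 10 networks per sequence and 10 repetitions per
#' network for each of the three algorithms (100 runs per sequence and
#' algorithm); smaller counts are useful for quick studies.
#'
#' @param sequences a [degree_sequence()] or list of them.
#' @param networks_per_sequence configuration-model draws per sequence.
#' @param reps_per_network rewiring repetitions per network and algorithm.
#' @param algorithms subset of `c("assortativity", "clustering",
#'   "geodesic")`.
#' @param rewiring_overrides named list of [rewiring_config()] arguments
#'   (`window`, `convergence`, `max_attempts`) applied to every run; by
#'   default each run uses the standard per-algorithm defaults derived from
#'   its network's edge count.
#' @param seed master seed. Every per-network and per-run seed is a
#'   deterministic function of it, so the whole experiment is reproducible.
#' @param out_dir output directory for trajectory CSVs, starting-network
#'   edge lists and the summary table.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sequences, networks_per_sequence = 10L,
                              reps_per_network = 10L,
                              algorithms = c("assortativity", "clustering", "geodesic"),
                              rewiring_overrides = list(), seed = 1L,
                              out_dir = tempfile("netrewire_exp")) {
  if (inherits(sequences, "degree_sequence")) sequences <- list(sequences)
  if (!length(sequences) ||
      !all(vapply(sequences, inherits, TRUE, "degree_sequence"))) {
    stop("`sequences` must be one or more degree_sequence objects")
  }
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (networks_per_sequence < 1L || reps_per_network < 1L) {
    stop("replicate counts must be at least 1")
  }
  structure(
    list(sequences = sequences,
         networks_per_sequence = as.integer(networks_per_sequence),
         reps_per_network = as.integer(reps_per_network),
         algorithms = algorithms, rewiring_overrides = rewiring_overrides,
         seed = as.integer(seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

# File helpers for trajectory CSVs: a '#'-comment header carries the schema
# version; metadata columns precede the snapshot columns. NA (the
# undefined-assortativity sentinel) serializes as an empty cell.
write_trajectory <- function(traj, path, meta = list()) {
  df <- cbind(as.data.frame(meta, stringsAsFactors = FALSE), traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# netrewire trajectory v1", con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory CSV written by [run_experiment()]
#'
#' @param path file path.
#' @return A `data.frame` with metadata columns (`sequence`, `network`,
#'   `rep`, `algorithm`), then `attempt`, `successes` and the property
#'   columns. Empty assortativity cells read back as `NA`.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run a full rewiring experiment
#'
#' For each degree sequence, draws `networks_per_sequence`
#' configuration-model networks and takes their giant components as
#' starting points; for each network, repetition and algorithm, runs
#' [run_rewiring()] with per-algorithm default parameters (or the
#' configured overrides). Each run's trajectory is written to one CSV file;
#' every starting network is persisted as an edge list so initial property
#' values can be audited; and a summary table reports, per sequence and
#' algorithm, the mean initial and final value of every property across
#' runs. Fully deterministic given the master seed. Individual run failures
#' are recorded in the returned `errors` element rather than aborting the
#' experiment.
#'
#' @param config an [experiment_config()].
#' @return Invisibly, a list with `summary` (data.frame), `files`
#'   (trajectory file paths) and `errors` (named list of condition
#'   messages, empty on success).
#' @examples
#' \donttest{
#' sq <- synth_degree_sequence(40, 4, 0.2, name = "demo", seed = 1)
#' cfg <- experiment_config(sq, networks_per_sequence = 2,
#'                          reps_per_network = 1,
#'                          algorithms = "assortativity", seed = 1)
#' res <- run_experiment(cfg)
#' res$summary[, c("sequence", "algorithm", "phase", "assortativity")]
#' }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop("cannot create output directory '", config$out_dir, "'")
  }
  S <- length(config$sequences)
  NN <- config$networks_per_sequence
  NR <- config$reps_per_network
  algs <- config$algorithms
  set.seed(config$seed)
  net_seeds <- matrix(sample.int(.Machine$integer.max - 1L, S * NN), nrow = S)
  run_seeds <- array(sample.int(.Machine$integer.max - 1L, S * NN * NR * length(algs)),
                     dim = c(S, NN, NR, length(algs)))

  files <- character(0)
  errors <- list()
  first_last <- list()
  for (si in seq_len(S)) {
    sq <- config$sequences[[si]]
    for (ni in seq_len(NN)) {
      set.seed(net_seeds[si, ni])
      g <- giant_component(configuration_model(sq))
      start_path <- file.path(config$out_dir,
                              sprintf("start_%s_net%02d.txt", sq$name, ni))
      write_edge_list(g, start_path)
      for (ri in seq_len(NR)) {
        for (ai in seq_along(algs)) {
          run_id <- sprintf("%s_net%02d_rep%02d_%s", sq$name, ni, ri, algs[ai])
          rc_args <- c(list(algorithm = algs[ai], edges = igraph::ecount(g),
                            seed = run_seeds[si, ni, ri, ai]),
                       config$rewiring_overrides)
          res <- tryCatch(
            run_rewiring(g, do.call(rewiring_config, rc_args)),
            error = function(e) e
          )
          if (inherits(res, "error")) {
            errors[[run_id]] <- conditionMessage(res)
            next
          }
          traj <- res$trajectory
          path <- file.path(config$out_dir, paste0("traj_", run_id, ".csv"))
          write_trajectory(traj, path,
                           meta = list(sequence = sq$name, network = ni,
                                       rep = ri, algorithm = algs[ai]))
          files <- c(files, path)
          first_last[[run_id]] <- data.frame(
            sequence = sq$name, algorithm = algs[ai],
            phase = c("initial", "final"),
            rbind(traj[1L, -(1:2)], traj[nrow(traj), -(1:2)]),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(first_last) == 0L) stop("no experiment run succeeded")
  all_fl <- do.call(rbind, first_last)
  rownames(all_fl) <- NULL
  prop_cols <- setdiff(names(all_fl), c("sequence", "algorithm", "phase"))
  summary <- stats::aggregate(all_fl[prop_cols],
                              by = all_fl[c("sequence", "algorithm", "phase")],
                              FUN = mean)
  summary <- summary[order(summary$sequence, summary$algorithm,
                           summary$phase == "final"), , drop = FALSE]
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE, na = "")
  invisible(list(summary = summary, files = files, errors = errors))
}

#' Property-pair trajectory plot
#'
#' Scatter of two property columns across trajectory snapshots, with the
#' colour gradient (lighter to darker) indicating the increase in number of
#' rewiring attempts, faceted by algorithm when several are present. This
#' is the standard view for judging whether manipulating one property
#' drags another along with it.
#'
#' @param trajectories a `data.frame` of (possibly row-bound) trajectories
#'   as returned by [read_trajectory()] or found in `run_rewiring()$trajectory`.
#' @param property_x,property_y property column names to plot.
#' @param output optional file path (`.png`, `.pdf`, `.svg`); when given the
#'   plot is also saved there.
#' @return The ggplot object.
#' @export
pair_plot <- function(trajectories, property_x, property_y, output = NULL) {
  trajectories <- as.data.frame(trajectories)
  if (nrow(trajectories) == 0L) stop("no trajectory snapshots to plot")
  valid <- setdiff(names(trajectories), c("sequence", "network", "rep", "algorithm"))
  for (p in c(property_x, property_y)) {
    if (!p %in% names(trajectories)) {
      stop("unknown property '", p, "'; valid columns: ",
           paste(valid, collapse = ", "))
    }
  }
  pl <- ggplot2::ggplot(
    trajectories,
    ggplot2::aes(x = .data[[property_x]], y = .data[[property_y]],
                 colour = .data[["attempt"]])
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(direction = -1, name = "attempt") +
    ggplot2::labs(x = property_x, y = property_y) +
    ggplot2::theme_minimal()
  if ("algorithm" %in% names(trajectories) &&
      length(unique(trajectories$algorithm)) > 1L) {
    pl <- pl + ggplot2::facet_wrap(~algorithm, scales = "free")
  }
  if (!is.null(output)) ggplot2::ggsave(output, pl, width = 6, height = 4)
  pl
}
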