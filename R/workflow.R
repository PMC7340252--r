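#' Configuration of the self-supervised picking workflow
#'
#' Bundles the decision rules of the training loop: the %/Res class cutoff,
#' the 90% initial-selection stop, the 70% convergence rule with its
#' three-iteration cap, and the 0.9 picking probability cut, together with
#' the picker, crop-geometry and CNN settings.
#'
#' @param particle_size particle diameter in unbinned pixels
#' @param ratio_cutoff %/Res class-selection cutoff (default 0.1)
#' @param init_stop_fraction initial selection stops once this fraction of
#'   input particles is selected (default 0.90)
#' @param convergence_fraction training converges once this fraction of
#'   CNN picks falls in selected classes (default 0.70)
#' @param max_train_iterations iteration cap; the last model is used for
#'   production if convergence is not reached (default 3)
#' @param p_min picking probability cut (default 0.9)
#' @param epochs CNN training epochs per iteration (default 30)
#' @param neg_per_pos negatives per positive in training sets
#' @param bin_size,threshold,invert,noise_k ab initio picker settings, see
#'   [localpicker_params()]
#' @param conv_filters,dense_hidden CNN architecture, see [cnn_config()]
#' @param stride,box_px,bin_factor scan/crop geometry overrides
#' @param seed master seed; all stage seeds are derived from it
#' @return an object of class `workflow_config`
#' @export
workflow_config <- function(particle_size, ratio_cutoff = 0.1,
                            init_stop_fraction = 0.90,
                            convergence_fraction = 0.70,
                            max_train_iterations = 3L, p_min = 0.9,
                            epochs = 30L, neg_per_pos = 1,
                            bin_size = 9L, threshold = 0.0015,
                            invert = FALSE, noise_k = 4,
                            conv_filters = c(32L, 64L, 128L),
                            dense_hidden = 128L, stride = NULL,
                            box_px = NULL, bin_factor = NULL, seed = 0L) {
  for (f in c(init_stop_fraction, convergence_fraction)) {
    if (f <= 0 || f > 1) stop("fractions must lie in (0, 1]")
  }
  if (max_train_iterations < 1) stop("max_train_iterations must be >= 1")
  structure(list(particle_size = particle_size, ratio_cutoff = ratio_cutoff,
                 init_stop_fraction = init_stop_fraction,
                 convergence_fraction = convergence_fraction,
                 max_train_iterations = as.integer(max_train_iterations),
                 p_min = p_min, epochs = as.integer(epochs),
                 neg_per_pos = neg_per_pos, bin_size = as.integer(bin_size),
                 threshold = threshold, invert = invert, noise_k = noise_k,
                 conv_filters = conv_filters, dense_hidden = dense_hidden,
                 stride = stride, box_px = box_px, bin_factor = bin_factor,
                 seed = as.integer(seed)),
            class = "workflow_config")
}

as_micrograph_list <- function(micrographs) {
  if (inherits(micrographs, "micrograph")) return(list(micrographs))
  stopifnot(is.list(micrographs))
  micrographs
}

extract_all <- function(micrographs, coords, config) {
  geom <- crop_geometry(config$particle_size, config$box_px,
                        config$bin_factor)
  stacks <- lapply(micrographs, function(mg) {
    extract_particles(mg, coords[coords$micrograph_id == mg$id, ,
                                 drop = FALSE],
                      geom$box_px, geom$bin_factor)
  })
  combine_stacks(stacks)
}

#' Initialize the workflow: ab initio picks plus iterative 2D selection
#'
#' Runs [localpick()] on every subset micrograph (or uses manually picked
#' coordinates when supplied, skipping the picker entirely), extracts the
#' picks and applies [iterate_selection()] until the initial stop fraction
#' is reached. The surviving particles seed the first CNN training round.
#'
#' @param micrographs list of [micrograph()] (the training subset; a
#'   handful of micrographs suffices)
#' @param config a [workflow_config()]
#' @param manual_coords optional data.frame (`micrograph_id`, `x`, `y`) of
#'   manual picks replacing the ab initio stage
#' @return an object of class `pick_workflow` holding the filtered
#'   coordinate set and iteration ledger
#' @export
workflow_init <- function(micrographs, config, manual_coords = NULL) {
  micrographs <- as_micrograph_list(micrographs)
  if (length(micrographs) == 0) stop("no micrographs supplied")
  if (length(micrographs) > 40) {
    warning("initialization subsets are typically 20-40 micrographs; got ",
            length(micrographs))
  }
  if (is.null(manual_coords)) {
    lp <- localpicker_params(config$particle_size, config$bin_size,
                             config$threshold, config$invert,
                             config$noise_k)
    coords <- do.call(rbind, lapply(micrographs, localpick, params = lp))
  } else {
    coords <- manual_coords
  }
  if (nrow(coords) == 0) stop("initial picking produced no candidates")
  stack <- extract_all(micrographs, coords, config)
  coords <- stack$source
  sel <- iterate_selection(stack, cutoff = config$ratio_cutoff,
                           stop_fraction = config$init_stop_fraction,
                           seed = derive_seed(config$seed, 101L))
  kept <- coords[sel$indices, , drop = FALSE]
  if (nrow(kept) < 10) {
    stop("only ", nrow(kept), " particles survived initial selection; ",
         "need at least 10")
  }
  if (nrow(kept) < 100) {
    warning("only ", nrow(kept), " particles survived initial selection; ",
            "at least 100 are recommended for CNN training")
  }
  structure(list(iteration = 0L, model = NULL, coords = kept,
                 qualified_fraction = NA_real_, converged = FALSE,
                 init_states = sel$states, config = config,
                 n_initial_picks = nrow(stack$source),
                 ledger = data.frame()),
            class = "pick_workflow")
}

#' Run one train / pick / classify / select iteration
#'
#' Trains a fresh CNN on the current particle set (with freshly sampled
#' negatives), picks all subset micrographs with it, classifies the picks
#' in 2D, applies the %/Res selection and replaces the current particle
#' set by the picks in selected classes. The qualified fraction (selected
#' picks over total picks) drives [check_convergence()].
#'
#' @param state a `pick_workflow`
#' @param micrographs the same micrograph subset used at initialization
#' @param config a [workflow_config()]
#' @return the updated `pick_workflow`
#' @export
run_iteration <- function(state, micrographs, config = state$config) {
  stopifnot(inherits(state, "pick_workflow"))
  micrographs <- as_micrograph_list(micrographs)
  it <- state$iteration + 1L
  seed_it <- derive_seed(config$seed, 200L + it)

  ts <- make_training_set(micrographs, state$coords, config$particle_size,
                          neg_per_pos = config$neg_per_pos,
                          box_px = config$box_px,
                          bin_factor = config$bin_factor, seed = seed_it)
  cfg <- cnn_config(conv_filters = config$conv_filters,
                    dense_hidden = config$dense_hidden,
                    epochs = config$epochs, seed = seed_it)
  model <- build_cnn(cfg)
  model <- train_cnn(model, ts$crops, ts$labels)

  picks <- do.call(rbind, lapply(micrographs, function(mg) {
    cnn_pick(model, mg, config$particle_size, p_min = config$p_min,
             stride = config$stride, box_px = config$box_px,
             bin_factor = config$bin_factor)
  }))
  if (is.null(picks) || nrow(picks) == 0) {
    stop("the CNN picked no particles at p_min = ", config$p_min,
         "; consider lowering p_min")
  }
  stack <- extract_all(micrographs, picks, config)
  picks <- stack$source
  K <- num_classes(nrow(picks))
  cls <- classify2d(stack, K, seed = derive_seed(config$seed, 300L + it))
  sel <- select_classes(cls, config$ratio_cutoff)
  qf <- length(sel$particle_indices) / nrow(picks)

  state$iteration <- it
  state$model <- model
  state$last_picks <- picks       # raw CNN picks, before class filtering
  state$coords <- picks[sel$particle_indices, , drop = FALSE]
  state$qualified_fraction <- qf
  state$converged <- qf >= config$convergence_fraction
  state$ledger <- rbind(state$ledger, data.frame(
    iteration = it, n_train_pos = sum(ts$labels == 1),
    n_picked = nrow(picks), n_qualified = length(sel$particle_indices),
    qualified_fraction = qf, seed = seed_it,
    final_val_accuracy = utils::tail(model$history$val_accuracy, 1)))
  state
}

#' Convergence decision for the training loop
#'
#' @param state a `pick_workflow` with at least one completed iteration
#' @param config a [workflow_config()]
#' @return `"converged"` when the qualified fraction reaches the
#'   convergence fraction, `"cap_reached"` when the iteration cap is hit
#'   without convergence (the last model is still used for production),
#'   `"continue"` otherwise
#' @export
check_convergence <- function(state, config = state$config) {
  stopifnot(inherits(state, "pick_workflow"))
  if (state$iteration < 1) stop("no completed iteration to judge")
  if (state$qualified_fraction >= config$convergence_fraction) {
    "converged"
  } else if (state$iteration >= config$max_train_iterations) {
    "cap_reached"
  } else {
    "continue"
  }
}

#' Run the full self-supervised picking workflow
#'
#' [workflow_init()] followed by [run_iteration()] until
#' [check_convergence()] reports convergence or the iteration cap.
#'
#' @inheritParams workflow_init
#' @param verbose print per-iteration progress
#' @return the final `pick_workflow`; its `model` is always usable for
#'   production picking
#' @export
run_workflow <- function(micrographs, config, manual_coords = NULL,
                         verbose = FALSE) {
  micrographs <- as_micrograph_list(micrographs)
  state <- workflow_init(micrographs, config, manual_coords)
  if (verbose) {
    message("initialization: ", nrow(state$coords), " of ",
            state$n_initial_picks, " initial picks kept")
  }
  repeat {
    state <- run_iteration(state, micrographs, config)
    decision <- check_convergence(state, config)
    if (verbose) {
      message(sprintf("iteration %d: %d picks, qualified %.1f%% -> %s",
                      state$iteration, state$ledger$n_picked[state$iteration],
                      100 * state$qualified_fraction, decision))
    }
    if (decision != "continue") {
      state$decision <- decision
      return(state)
    }
  }
}

#' @export
print.pick_workflow <- function(x, ...) {
  cat(sprintf("<pick_workflow: iteration %d, %d particles, %s>\n",
              x$iteration, nrow(x$coords),
              if (isTRUE(x$converged)) "converged"
              else if (x$iteration == 0) "initialized" else "not converged"))
  if (nrow(x$ledger) > 0) print(x$ledger, row.names = FALSE)
  invisible(x)
}

#' Production picking over a full micrograph set
#'
#' Applies [cnn_pick()] with the converged (or capped) model to every
#' micrograph. Micrograph entries may be paths; unreadable files are
#' logged, skipped and reported. With an output directory, one coordinate
#' STAR per micrograph is written and micrographs whose output already
#' exists are skipped unless `overwrite = TRUE`, making reruns resumable.
#'
#' @param model a trained `cryo_cnn`
#' @param micrographs list of [micrograph()] objects and/or MRC paths
#' @param config a [workflow_config()]
#' @param out_dir optional output directory for per-micrograph STAR files
#' @param overwrite recompute micrographs with existing outputs
#' @return list with `coords` (per-micrograph pick data.frames) and
#'   `summary` (total picks, per-micrograph counts, failures, skipped)
#' @export
production_pick <- function(model, micrographs, config, out_dir = NULL,
                            overwrite = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (inherits(micrographs, "micrograph")) micrographs <- list(micrographs)
  coords <- list()
  counts <- integer(0)
  failures <- character(0)
  skipped <- character(0)
  for (entry in micrographs) {
    id <- if (inherits(entry, "micrograph")) entry$id
          else sub("\\.[^.]*$", "", basename(entry))
    out_path <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0(id, "_picks.star"))
    } else NULL
    if (!is.null(out_path) && file.exists(out_path) && !overwrite) {
      skipped <- c(skipped, id)
      coords[[id]] <- read_star_coords(out_path)
      coords[[id]]$micrograph_id <- id
      counts[id] <- nrow(coords[[id]])
      next
    }
    mg <- tryCatch(
      if (inherits(entry, "micrograph")) entry else read_mrc(entry),
      error = function(e) e)
    if (inherits(mg, "error")) {
      warning("skipping unreadable micrograph '", id, "': ",
              conditionMessage(mg))
      failures <- c(failures, id)
      next
    }
    picks <- cnn_pick(model, mg, config$particle_size,
                      p_min = config$p_min, stride = config$stride,
                      box_px = config$box_px,
                      bin_factor = config$bin_factor)
    coords[[mg$id]] <- picks
    counts[mg$id] <- nrow(picks)
    if (!is.null(out_path)) {
      write_star_coords(data.frame(x = picks$x, y = picks$y,
                                   score = picks$score), out_path)
    }
  }
  list(coords = coords,
       summary = list(total_picks = sum(counts), per_micrograph = counts,
                      failures = failures, skipped = skipped))
}
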