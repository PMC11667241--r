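#' One-shot (patient-specific) groupwise registration
#'
#' Trains the registration network from scratch on the single phase-image
#' set to be registered: the set is repeatedly fed forward, the groupwise
#' loss (negative LNCC to the implicit template plus spatial bending energy,
#' temporal diffusion and the zero-mean deformation constraint) is
#' backpropagated, and the parameters updated with Adam. Convergence is
#' declared when the loss differs from the moving average of the previous
#' `converge_window` iterations by less than `converge_tol`; if the
#' iteration cap is reached first a warning reports the final loss delta and
#' the fields are returned anyway.
#'
#' @param images a [phase_image_set()] of normalized (`[0, 1]`) volumes.
#' @param config a [registration_config()].
#' @param net optionally a pre-built [build_network()] to continue from.
#' @param verbose print the loss every 25 iterations.
#' @return a list with `dvfs` (array `(nx,ny,nz,3,N)`, voxel units), `net`
#'   (the trained network), `loss_trace`, `iterations` and `converged`.
#' @export
one_shot_register <- function(images, config = registration_config(),
                              net = NULL, verbose = FALSE) {
  if (images$n < 2) stop("groupwise registration needs at least two phases")
  stack <- phase_stack(images)
  if (is.null(net))
    net <- build_network(network_spec(images$n, config$widths,
                                      config$downsample), config$seed)
  state <- adam_init(net$params)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    fwd <- network_forward(net, stack)
    lg <- total_loss_grad(stack, fwd$dvf, config)
    trace[it] <- lg$loss
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %4d  loss %.6f", it, lg$loss))
    w <- config$converge_window
    if (it > w) {
      ma <- mean(trace[(it - w):(it - 1)])
      if (abs(lg$loss - ma) < config$converge_tol) { converged <- TRUE; break }
    }
    grads <- network_backward(net, fwd$cache, lg$grad)
    st <- adam_step(net$params, grads, state, config$learning_rate)
    net$params <- st$params
    state <- st$state
  }
  if (!converged) {
    w <- config$converge_window
    delta <- if (length(trace) > w)
      abs(trace[length(trace)] - mean(trace[(length(trace) - w):(length(trace) - 1)]))
    else NA_real_
    warning(sprintf(
      "one-shot registration hit the iteration cap (%d); final loss delta %.3g",
      config$max_iter, delta))
  }
  fwd <- network_forward(net, stack, want_cache = FALSE)
  list(dvfs = fwd$dvf, net = net, loss_trace = trace,
       iterations = length(trace), converged = converged)
}

#' Train a population registration model
#'
#' Optimizes the same groupwise loss over a collection of phase-image sets
#' (batch size 1, fixed epoch budget). The resulting network can be applied
#' to a new, unseen set in a single forward pass with [predict_dvfs()].
#'
#' @param training_sets list of [phase_image_set()] objects with identical
#'   N and grid.
#' @param config a [registration_config()]; `population_epochs` sets the
#'   epoch budget.
#' @param verbose print the running loss once per epoch.
#' @return a list with `net`, `loss_trace` (one value per update) and
#'   `iterations` (`= epochs x sets`).
#' @export
train_population <- function(training_sets, config = registration_config(),
                             verbose = FALSE) {
  if (length(training_sets) < 1) stop("need at least one training set")
  N <- training_sets[[1]]$n
  d0 <- dim(training_sets[[1]]$volumes[[1]]$data)
  for (s in training_sets) {
    if (s$n != N || !identical(dim(s$volumes[[1]]$data), d0))
      stop("heterogeneous grids/phase counts: resample the training sets ",
           "to a common grid first")
  }
  stacks <- lapply(training_sets, phase_stack)
  net <- build_network(network_spec(N, config$widths, config$downsample),
                       config$seed)
  state <- adam_init(net$params)
  trace <- numeric(0)
  for (ep in seq_len(config$population_epochs)) {
    for (s in seq_along(stacks)) {
      fwd <- network_forward(net, stacks[[s]])
      lg <- total_loss_grad(stacks[[s]], fwd$dvf, config)
      trace <- c(trace, lg$loss)
      grads <- network_backward(net, fwd$cache, lg$grad)
      st <- adam_step(net$params, grads, state, config$learning_rate)
      net$params <- st$params
      state <- st$state
    }
    if (verbose)
      message(sprintf("epoch %3d  mean loss %.6f", ep,
                      mean(utils::tail(trace, length(stacks)))))
  }
  list(net = net, loss_trace = trace, iterations = length(trace))
}

#' Predict displacement fields with a trained model (single pass)
#'
#' One forward pass, no parameter updates.
#'
#' @param net a trained [build_network()] / [train_population()] network.
#' @param images a [phase_image_set()] with the N the network was built for.
#' @return array `(nx, ny, nz, 3, N)` of voxel-unit displacements.
#' @export
predict_dvfs <- function(net, images) {
  if (images$n != net$spec$n_phases)
    stop(sprintf("network expects %d phases, got %d", net$spec$n_phases,
                 images$n))
  network_forward(net, phase_stack(images), want_cache = FALSE)$dvf
}
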