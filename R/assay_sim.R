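# Mechanistic simulator of the 4-hour calcein cytotoxicity assay.
#
# Every fluorescent entity in a well is one row of a particle table:
#   kind        live_cell | necrotic_remnant | apoptotic_body
#   calcein     retained calcein, AU (>= 0)
#   diameter_um physical size
#   x_um, y_um  position in the counting chamber
# Calcein not retained in a particle is in the supernatant; the simulator
# conserves total loaded calcein exactly.

particle_frame <- function(kind = character(), calcein = numeric(),
                           diameter_um = numeric(), x_um = numeric(),
                           y_um = numeric()) {
  data.frame(kind = kind, calcein = calcein, diameter_um = diameter_um,
             x_um = x_um, y_um = y_um, stringsAsFactors = FALSE)
}

#' Draw per-cell calcein loads
#'
#' Loading efficiency varies between cells; loads are drawn from a lognormal
#' distribution parameterized by its mean and coefficient of variation
#' (strictly positive, right-skewed, two parameters). `load_cv = 0`
#' degenerates to identical loads equal to the mean.
#'
#' @param n_cells number of cells.
#' @param params an [assay_params()] object (`load_mean`, `load_cv` used).
#' @param seed RNG seed.
#' @return numeric vector of `n_cells` strictly positive loads (AU).
#' @export
load_calcein <- function(n_cells, params, seed) {
  n_cells <- check_count(n_cells, "n_cells")
  withr::with_seed(seed, load_calcein_(n_cells, params))
}

load_calcein_ <- function(n_cells, params) {
  sdlog <- sqrt(log1p(params$load_cv^2))
  meanlog <- log(params$load_mean) - sdlog^2 / 2
  rlnorm(n_cells, meanlog = meanlog, sdlog = sdlog)
}

#' Lyse one target cell
#'
#' Necrosis-like lysis empties the cell into the supernatant except for a
#' `necrotic_retention` fraction entrapped in a single cell-sized remnant.
#' Apoptotic lysis fragments the cell into `bodies_per_cell` apoptotic
#' bodies that jointly retain an `apoptotic_retention` fraction, split
#' across bodies by a symmetric Dirichlet draw renormalized to the retained
#' total. Released plus retained equals the input calcein exactly.
#'
#' @param calcein calcein content of the cell, AU.
#' @param mode `"necrotic"` or `"apoptotic"`.
#' @param params an [assay_params()] object.
#' @param seed RNG seed (the apoptotic split is random).
#' @return a list with `released` (AU) and `fragments` (particle table).
#' @export
lyse_cell <- function(calcein, mode, params, seed = 1L) {
  if (!is.numeric(calcein) || length(calcein) != 1L || calcein < 0) {
    abort_param("`calcein` must be a single value >= 0")
  }
  if (!is.character(mode) || length(mode) != 1L ||
      !mode %in% c("necrotic", "apoptotic")) {
    abort_param("`mode` must be \"necrotic\" or \"apoptotic\"")
  }
  withr::with_seed(seed, lyse_cell_(calcein, mode, params))
}

lyse_cell_ <- function(calcein, mode, params) {
  if (mode == "necrotic") {
    retained <- params$necrotic_retention * calcein
    frags <- particle_frame(kind = "necrotic_remnant", calcein = retained,
                            diameter_um = params$live_diameter_um,
                            x_um = NA_real_, y_um = NA_real_)
  } else {
    b <- params$bodies_per_cell
    retained_total <- params$apoptotic_retention * calcein
    w <- rgamma(b, shape = params$body_split_conc)
    w <- w / sum(w)
    frags <- particle_frame(kind = rep("apoptotic_body", b),
                            calcein = w * retained_total,
                            diameter_um = rep(params$body_diameter_um, b),
                            x_um = rep(NA_real_, b), y_um = rep(NA_real_, b))
    retained <- retained_total
  }
  list(released = calcein - retained, fragments = frags)
}

#' Simulate one assay well to its 4-hour endpoint
#'
#' Maximum-release wells (Triton X-100) solubilize every cell: all loaded
#' calcein is in the supernatant and no fluorescent particle remains.
#' Spontaneous wells leak a fixed `leak_frac` of each cell's calcein.
#' Test wells kill each target independently with the E:T-specific kill
#' probability; killed cells die apoptotically with probability
#' `apoptotic_frac`, otherwise necrosis-like, and are lysed as in
#' [lyse_cell()]; survivors leak like the spontaneous control. Particle
#' positions are uniform over the square counting chamber.
#'
#' @param spec a [well_spec()].
#' @param params an [assay_params()].
#' @return an object of class `well_state`: list with `spec`, `particles`
#'   (particle table), `supernatant_calcein` and `total_loaded` (AU).
#' @export
simulate_well <- function(spec, params) {
  if (!inherits(spec, "well_spec")) abort_param("`spec` must be a well_spec")
  if (!inherits(params, "assay_params")) {
    abort_param("`params` must be an assay_params object")
  }
  kill_frac <- if (spec$role == "test") kill_frac_for_et(params, spec$et_ratio) else 0
  withr::with_seed(spec$seed, simulate_well_(spec, params, kill_frac))
}

simulate_well_ <- function(spec, params, kill_frac) {
  n <- spec$n_targets
  loads <- load_calcein_(n, params)
  total <- sum(loads)

  if (spec$role == "maximum") {
    return(new_well_state(spec, particle_frame(), supernatant = total,
                          total = total))
  }

  killed <- if (spec$role == "test") runif(n) < kill_frac else rep(FALSE, n)
  apoptotic <- killed & (runif(n) < params$apoptotic_frac)
  necrotic <- killed & !apoptotic

  # survivors leak a fixed fraction, like the spontaneous control
  surv_loads <- loads[!killed]
  parts <- list(particle_frame(
    kind = rep("live_cell", length(surv_loads)),
    calcein = (1 - params$leak_frac) * surv_loads,
    diameter_um = rep(params$live_diameter_um, length(surv_loads)),
    x_um = rep(NA_real_, length(surv_loads)),
    y_um = rep(NA_real_, length(surv_loads))))
  supernatant <- params$leak_frac * sum(surv_loads)

  nec_loads <- loads[necrotic]
  if (length(nec_loads)) {
    parts[[length(parts) + 1L]] <- particle_frame(
      kind = rep("necrotic_remnant", length(nec_loads)),
      calcein = params$necrotic_retention * nec_loads,
      diameter_um = rep(params$live_diameter_um, length(nec_loads)),
      x_um = rep(NA_real_, length(nec_loads)),
      y_um = rep(NA_real_, length(nec_loads)))
    supernatant <- supernatant +
      (1 - params$necrotic_retention) * sum(nec_loads)
  }

  apo_loads <- loads[apoptotic]
  if (length(apo_loads)) {
    b <- params$bodies_per_cell
    w <- matrix(rgamma(length(apo_loads) * b, shape = params$body_split_conc),
                nrow = length(apo_loads))
    w <- w / rowSums(w)
    retained <- params$apoptotic_retention * apo_loads
    parts[[length(parts) + 1L]] <- particle_frame(
      kind = rep("apoptotic_body", length(apo_loads) * b),
      calcein = as.vector(t(w * retained)),
      diameter_um = rep(params$body_diameter_um, length(apo_loads) * b),
      x_um = rep(NA_real_, length(apo_loads) * b),
      y_um = rep(NA_real_, length(apo_loads) * b))
    supernatant <- supernatant +
      (1 - params$apoptotic_retention) * sum(apo_loads)
  }

  particles <- do.call(rbind, parts)
  np <- nrow(particles)
  particles$x_um <- runif(np, 0, params$chamber_um)
  particles$y_um <- runif(np, 0, params$chamber_um)
  rownames(particles) <- NULL

  new_well_state(spec, particles, supernatant = supernatant, total = total)
}

new_well_state <- function(spec, particles, supernatant, total) {
  structure(list(spec = spec, particles = particles,
                 supernatant_calcein = supernatant, total_loaded = total),
            class = "well_state")
}

#' @export
print.well_state <- function(x, ...) {
  counts <- table(factor(x$particles$kind,
                         levels = c("live_cell", "necrotic_remnant",
                                    "apoptotic_body")))
  cat(sprintf(
    "<well_state> role=%s E:T=%g n_targets=%d\n  particles: %d live, %d remnants, %d bodies\n  supernatant %.4g / %.4g AU loaded\n",
    x$spec$role, x$spec$et_ratio, x$spec$n_targets,
    counts[["live_cell"]], counts[["necrotic_remnant"]],
    counts[["apoptotic_body"]],
    x$supernatant_calcein, x$total_loaded))
  invisible(x)
}
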