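#' Simulation configuration
#'
#' Parameters of the synthetic spatial transcriptomics generator. The
#' generator emulates the two structures the imputation model exploits —
#' spatially contiguous cell-type domains (layered tissue bands with
#' block-structured expression programs) and spatially smooth expression
#' gradients (low-frequency sinusoidal fields) — plus zero-inflated
#' observation dropout on Poisson counts.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_layers number of contiguous horizontal tissue bands.
#' @param grid `"hex"` (pitch-1 hexagonal lattice, Visium-like) or
#'   `"square"`.
#' @param n_types number of cell types; each band has a dominant type but
#'   every type recurs scattered across the tissue, so expression
#'   similarity links faraway cells that spatial proximity cannot.
#' @param type_mix probability that a cell carries its band's dominant type
#'   (1 = types fully determined by band).
#' @param program_rank rank of the shared low-dimensional structure mixed
#'   into the block-structured type programs.
#' @param spatial_signal_scale,type_signal_scale relative strength of the
#'   smooth spatial field and the cell-type programs (either may be 0 to
#'   switch that structure off).
#' @param noise_scale sd of per-entry Gaussian noise on the log-rate scale.
#' @param base_rate multiplicative Poisson rate scale; together with
#'   `dropout_rate` it sets the observed nonzero density.
#' @param dropout_rate independent Bernoulli zeroing probability in `[0, 1)`.
#' @param seed integer; the draw is deterministic per seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 500, n_genes = 200, n_layers = 4,
                       grid = c("hex", "square"), n_types = n_layers,
                       type_mix = 0.6, program_rank = 3,
                       spatial_signal_scale = 1.5, type_signal_scale = 2.5,
                       noise_scale = 0.3, base_rate = 3,
                       dropout_rate = 0.7, seed = 1L) {
  grid <- match.arg(grid)
  stopifnot(n_cells >= 1, n_genes >= 1, n_layers >= 1, n_types >= 1,
            type_mix >= 0, type_mix <= 1,
            dropout_rate >= 0, dropout_rate < 1, base_rate > 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_layers = as.integer(n_layers), grid = grid,
                 n_types = as.integer(n_types), type_mix = type_mix,
                 program_rank = as.integer(program_rank),
                 spatial_signal_scale = spatial_signal_scale,
                 type_signal_scale = type_signal_scale,
                 noise_scale = noise_scale, base_rate = base_rate,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Simulate a spatial transcriptomics dataset with known ground truth
#'
#' Cells sit on a pitch-1 lattice partitioned into `n_layers` contiguous
#' horizontal bands. The Poisson log-rate of cell c, gene g sums a
#' layer-program term (block-structured marker genes per band), a smooth
#' sinusoidal spatial field, and Gaussian noise; the rate is
#' `base_rate * softplus(.)`, counts are Poisson, and observed zeros are
#' inflated by independent dropout.
#'
#' @param cfg a [sim_config].
#' @return list with `dataset` (an [expr_dataset]: observed counts, lattice
#'   coordinates, layer labels) and `truth` (class `sim_truth`: dense
#'   expected-rate matrix `rate`, `layer_labels`, `programs`,
#'   `expected_density` — the closed-form observed-nonzero probability
#'   `(1 - dropout) * (1 - exp(-rate))` averaged over entries — and the
#'   generating `config`).
#' @export
simulate_spatial <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_cells; m <- cfg$n_genes
  with_seed(cfg$seed, {
    coords <- lattice_coords(n, cfg$grid)
    # contiguous horizontal bands, equal cell counts
    band <- cut(rank(coords[, 2], ties.method = "first"),
                breaks = cfg$n_layers, labels = FALSE)
    # cell types: each band has a dominant type (probability type_mix) but
    # every type recurs scattered across bands, so faraway cells can share
    # an expression signature
    dominant <- ((band - 1L) %% cfg$n_types) + 1L
    ctype <- ifelse(stats::runif(n) < cfg$type_mix, dominant,
                    sample.int(cfg$n_types, n, replace = TRUE))
    # type programs: each gene markers one type, amplitude random, plus a
    # low-rank shared component so programs are correlated but distinct
    block <- ((seq_len(m) - 1L) %% cfg$n_types) + 1L
    amp <- stats::runif(m, 0.5, 1.5)
    P <- matrix(0, cfg$n_types, m)
    P[cbind(block, seq_len(m))] <- amp
    if (cfg$program_rank > 0) {
      U <- matrix(stats::rnorm(cfg$n_types * cfg$program_rank, sd = 0.2),
                  cfg$n_types)
      V <- matrix(stats::rnorm(cfg$program_rank * m, sd = 0.2),
                  cfg$program_rank)
      P <- P + U %*% V
    }
    type_term <- cfg$type_signal_scale * P[ctype, , drop = FALSE]
    # smooth field: two low-frequency plane waves per gene
    extent <- max(apply(coords, 2, function(v) diff(range(v))), 1)
    S <- matrix(0, n, m)
    for (w in 1:2) {
      lambda <- stats::runif(m, extent / 2, extent)       # wavelengths
      theta <- stats::runif(m, 0, 2 * pi)                 # directions
      phase <- stats::runif(m, 0, 2 * pi)
      a <- stats::runif(m, 0.3, 0.8)
      proj <- outer(coords[, 1], cos(theta)) + outer(coords[, 2], sin(theta))
      S <- S + sin(sweep(2 * pi * proj, 2, lambda, "/") +
                     matrix(phase, n, m, byrow = TRUE)) *
        matrix(a, n, m, byrow = TRUE)
    }
    eta <- type_term + cfg$spatial_signal_scale * S +
      matrix(stats::rnorm(n * m, sd = cfg$noise_scale), n, m)
    rate <- cfg$base_rate * softplus(eta)
    counts <- matrix(stats::rpois(n * m, rate), n, m)
    keep <- matrix(stats::rbinom(n * m, 1, 1 - cfg$dropout_rate), n, m)
    X <- counts * keep
  })
  if (sum(X) == 0) stop("simulation produced an empty matrix; raise base_rate")
  dataset <- expr_dataset(X, coords = coords,
                          layer_labels = paste0("L", band))
  truth <- structure(list(rate = rate, layer_labels = band,
                          cell_types = ctype, programs = P,
                          expected_density =
                            mean((1 - cfg$dropout_rate) * (1 - exp(-rate))),
                          config = cfg),
                     class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

lattice_coords <- function(n, grid) {
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  ij <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)[seq_len(n), ]
  if (grid == "hex") {
    cbind(x = ij$ix + 0.5 * (ij$iy %% 2), y = ij$iy * sqrt(3) / 2)
  } else cbind(x = as.numeric(ij$ix), y = as.numeric(ij$iy))
}

#' Packaged synthetic fixtures
#'
#' Named presets used throughout the tests and experiments:
#' \describe{
#'   \item{tiny}{30 cells x 20 genes, 2 bands — unit-test scale.}
#'   \item{layered}{500 x 200, both signal types, observed density ~0.25.}
#'   \item{smooth_only}{300 x 120, smooth spatial field only (layer programs
#'     off), so the expression-similarity graph carries no extra signal.}
#'   \item{type_only}{300 x 120, layer programs only, and the spatial
#'     coordinates are randomly permuted after generation, so the spatial
#'     graph is uninformative while expression marginals are untouched.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return as [simulate_spatial]: list with `dataset` and `truth`.
#' @export
make_fixture <- function(name = c("tiny", "layered", "smooth_only",
                                  "type_only"), seed = 1L) {
  if (!is.character(name) || !name[1] %in%
        c("tiny", "layered", "smooth_only", "type_only"))
    stop("unknown fixture '", name[1],
         "'; options: tiny, layered, smooth_only, type_only")
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(n_cells = 30, n_genes = 20, n_layers = 2,
                      type_mix = 1, base_rate = 1, dropout_rate = 0.2,
                      seed = seed),
    layered = sim_config(n_cells = 500, n_genes = 200, n_layers = 4,
                         seed = seed),
    smooth_only = sim_config(n_cells = 300, n_genes = 120, n_layers = 3,
                             type_signal_scale = 0, program_rank = 0,
                             spatial_signal_scale = 2.5, seed = seed),
    type_only = sim_config(n_cells = 300, n_genes = 120, n_layers = 3,
                           spatial_signal_scale = 0,
                           type_signal_scale = 2.5, seed = seed))
  out <- simulate_spatial(cfg)
  if (name == "type_only") {
    perm <- with_seed(seed + 7L, sample.int(nrow(out$dataset$coords)))
    cds <- out$dataset$coords[perm, , drop = FALSE]
    rownames(cds) <- out$dataset$cell_ids
    out$dataset$coords <- cds
  }
  out$name <- name
  out
}

#' Write a simulated dataset to disk
#'
#' Writes observed counts (MTX + sidecars), coordinates (CSV), the true
#' rate matrix (MTX), and layer labels (TSV).
#'
#' @param sim a [simulate_spatial] / [make_fixture] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$dataset, file.path(dir, "counts.mtx"))
  write_coords(sim$dataset$coords, file.path(dir, "coords.csv"))
  Matrix::writeMM(Matrix::Matrix(sim$truth$rate, sparse = TRUE),
                  file.path(dir, "true_rate.mtx"))
  utils::write.table(
    data.frame(cell = sim$dataset$cell_ids, layer = sim$dataset$layer_labels),
    file.path(dir, "layers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
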