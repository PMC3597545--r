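#' Configuration for the synthetic kinetics generator
#'
#' The generator emulates the statistical structure the detection model
#' assumes. Each (position, strand) carries a latent kinetic rate
#' `rate = context_effect(context) + position_deviation` on the transformed
#' scale: the context effect is an additive per-window-slot base effect
#' (drawn once per simulation and scaled so its standard deviation across
#' positions equals `context_effect_sd`), optionally plus an iid
#' per-distinct-context residual (`context_residual_frac` of the context
#' variance); position deviations are `N(0, position_noise_sd^2)` and model
#' the heterogeneity between homologous positions. Native and control share
#' a position's deviation (same molecule population); historical data get
#' independent deviations (an unrelated experiment). Each read adds its
#' movie's batch offset and `N(0, read_noise_sd^2)` noise; raw IPDs are
#' recovered by inverting the Box-Cox transform, giving a realistic
#' positive-skew raw scale on which the model's own assumptions hold
#' exactly. With `raw_exponential = TRUE` raw IPDs are instead drawn from
#' exponential distributions whose log-mean is the latent rate plus the
#' movie offset — the robustness mode in which transformed IPDs are only
#' approximately normal.
#'
#' Modified sites elevate IPDs of reads from modified molecules only
#' (sampled with probability `mod_proportion`) by `delta` at the cognate
#' base and by `delta * rel` at each footprint offset (offsets counted along
#' the sequenced strand).
#'
#' @param genome_length genome size in bp (ignored when `genome` is given)
#' @param genome optional named character vector to use as the reference
#' @param window generative [context_window()]
#' @param context_effect_sd,position_noise_sd,read_noise_sd variance
#'   components, transformed-IPD units
#' @param context_residual_frac fraction of context-effect variance carried
#'   by an iid per-distinct-context residual (default 0: purely additive)
#' @param n_movies,movie_offset_sd per-dataset batch structure
#' @param coverage_native,coverage_control,coverage_historical per-position
#'   single-strand coverages
#' @param modification list with either `motif` + `motif_offset` or explicit
#'   `sites` (data frame `ref_name`, `position`, `strand`), plus `delta`
#'   (transformed-IPD units), `footprint` (list of `list(offset=, rel=)`),
#'   and optional `n_sites` to methylate only that many evenly spaced motif
#'   occurrences
#' @param mod_proportion fraction of molecules modified at a modified site,
#'   in (0, 1]
#' @param transform [transform_params()] linking transformed and raw scales
#' @param raw_exponential draw raw IPDs from exponentials instead of
#'   inverting the transform
#' @param seed integer seed governing all randomness
#' @return a `sim_config` list
#' @export
sim_config <- function(genome_length = 3000L, genome = NULL,
                       window = context_window(6L, 1L),
                       context_effect_sd = 0.2, position_noise_sd = 0.1,
                       read_noise_sd = 0.5, context_residual_frac = 0,
                       n_movies = 4L, movie_offset_sd = 0.1,
                       coverage_native = 20L, coverage_control = 20L,
                       coverage_historical = 25L,
                       modification = list(motif = "GATC", motif_offset = 1L,
                                           delta = 1.0, footprint = list()),
                       mod_proportion = 1,
                       transform = transform_params(0.25, 0),
                       raw_exponential = FALSE,
                       seed = 1L) {
  stopifnot(context_effect_sd >= 0, position_noise_sd >= 0,
            read_noise_sd >= 0, movie_offset_sd >= 0,
            coverage_native >= 1L, coverage_control >= 1L,
            coverage_historical >= 1L,
            mod_proportion > 0, mod_proportion <= 1,
            context_residual_frac >= 0, context_residual_frac <= 1)
  structure(list(genome_length = as.integer(genome_length), genome = genome,
                 window = window, context_effect_sd = context_effect_sd,
                 position_noise_sd = position_noise_sd,
                 read_noise_sd = read_noise_sd,
                 context_residual_frac = context_residual_frac,
                 n_movies = as.integer(n_movies),
                 movie_offset_sd = movie_offset_sd,
                 coverage_native = as.integer(coverage_native),
                 coverage_control = as.integer(coverage_control),
                 coverage_historical = as.integer(coverage_historical),
                 modification = modification,
                 mod_proportion = mod_proportion,
                 transform = transform, raw_exponential = raw_exponential,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# additive per-slot base weights -> context effect per position
.context_effects <- function(contexts, weights) {
  ok <- !is.na(contexts)
  eff <- numeric(length(contexts))
  if (any(ok)) {
    chars <- do.call(rbind, strsplit(contexts[ok], "", fixed = TRUE))
    idx <- match(chars, c("A", "C", "G", "T"))
    dim(idx) <- dim(chars)
    e <- 0
    for (j in seq_len(ncol(chars))) e <- e + weights[j, idx[, j]]
    eff[ok] <- e
  }
  eff
}

#' Generate a synthetic SMRT kinetics dataset with ground truth
#'
#' See [sim_config()] for the generative model. Returns the genome, raw-scale
#' native/control/historical IPD tables, the truth set of modified sites,
#' and the latent per-position rates (for variance-decomposition checks).
#' Deterministic given the config seed.
#'
#' @param config a [sim_config()]
#' @return a `sim_output` list with elements `genome`, `native`, `control`,
#'   `historical`, `truth`, `latent`, `config`
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mod <- config$modification
  # genome: supplied, or drawn uniformly (re-drawn if a requested motif is
  # absent, up to 10 times)
  if (!is.null(config$genome)) {
    genome <- config$genome
  } else {
    for (try in 1:10) {
      genome <- c(chr = paste(sample(c("A", "C", "G", "T"),
                                     config$genome_length, replace = TRUE),
                              collapse = ""))
      if (is.null(mod$motif) ||
          nrow(motif_sites(genome, mod$motif, mod$motif_offset %||% 0L)))
        break
      if (try == 10L)
        stop("simulate_dataset: motif ", mod$motif,
             " absent after 10 genome draws")
    }
  }
  refs <- names(genome)
  # truth sites
  truth <- if (!is.null(mod$sites)) {
    truth_set(mod$sites)
  } else if (!is.null(mod$motif)) {
    st <- motif_sites(genome, mod$motif, mod$motif_offset %||% 0L)
    if (!nrow(st))
      stop("simulate_dataset: motif ", mod$motif, " absent from genome")
    if (!is.null(mod$n_sites) && nrow(st) > mod$n_sites) {
      st <- st[order(st$ref_name, st$position), , drop = FALSE]
      st <- st[round(seq(1L, nrow(st), length.out = mod$n_sites)), ,
               drop = FALSE]
    }
    truth_set(st)
  } else truth_set(data.frame(ref_name = character(), position = integer(),
                              strand = character()))
  # latent rates per (ref, position, strand)
  latent <- do.call(rbind, lapply(refs, function(rn) {
    len <- nchar(genome[[rn]])
    expand.grid(ref_name = rn, position = 0:(len - 1L), strand = .STRANDS,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  latent <- latent[order(latent$ref_name, latent$position, latent$strand), ]
  rownames(latent) <- NULL
  ctx <- rep(NA_character_, nrow(latent))
  for (rn in refs) {
    sel <- latent$ref_name == rn
    ctx[sel] <- extract_context(genome, rn, latent$position[sel],
                                latent$strand[sel], config$window)
  }
  L <- config$window$length
  w <- matrix(rnorm(L * 4L), L, 4L)
  w <- w - rowMeans(w)
  # every window slot contributes equal context-effect variance
  w <- w / sqrt(rowMeans(w^2))
  eff <- .context_effects(ctx, w)
  ok <- !is.na(ctx)
  if (config$context_effect_sd > 0 && sum(ok) > 1L && sd(eff[ok]) > 0) {
    add_sd <- config$context_effect_sd *
      sqrt(1 - config$context_residual_frac)
    scl <- add_sd / sd(eff[ok])
    w <- w * scl
    eff <- eff * scl
    if (config$context_residual_frac > 0) {
      ures <- rnorm(length(unique(ctx[ok])), 0,
                    config$context_effect_sd *
                      sqrt(config$context_residual_frac))
      names(ures) <- unique(ctx[ok])
      eff[ok] <- eff[ok] + ures[ctx[ok]]
    }
  } else {
    w[] <- 0; eff[] <- 0
  }
  latent$context <- ctx
  latent$effect <- eff
  latent$deviation <- rnorm(nrow(latent), 0, config$position_noise_sd)
  latent$rate <- latent$effect + latent$deviation
  # per-site shift map for the native sample: cognate base + footprint
  shift <- numeric(nrow(latent))
  key <- paste(latent$ref_name, latent$position, latent$strand)
  if (nrow(truth)) {
    delta <- mod$delta %||% 1.0
    shift[key %in% paste(truth$ref_name, truth$position, truth$strand)] <-
      delta
    for (fp in mod$footprint %||% list()) {
      off <- ifelse(truth$strand == "+", fp$offset, -fp$offset)
      fkey <- paste(truth$ref_name, truth$position + off, truth$strand)
      hit <- key %in% fkey
      shift[hit] <- shift[hit] + delta * fp$rel
    }
  }
  draw_table <- function(role, coverage, dev, shifts) {
    n_pos <- nrow(latent)
    idx <- rep(seq_len(n_pos), each = coverage)
    movie <- sprintf("%s_m%02d", role,
                     sample.int(config$n_movies, length(idx), replace = TRUE))
    moff <- rnorm(config$n_movies, 0, config$movie_offset_sd)
    loc <- latent$effect[idx] + dev[idx] + shifts[idx] *
      (rbinom(length(idx), 1L, config$mod_proportion))
    if (config$raw_exponential) {
      raw <- rexp(length(idx)) *
        exp(loc + moff[as.integer(sub(".*_m", "", movie))])
    } else {
      y <- loc + moff[as.integer(sub(".*_m", "", movie))] +
        rnorm(length(idx), 0, config$read_noise_sd)
      lam <- config$transform$lam
      if (lam != 0) y <- pmax(y, -1 / lam + 1e-6)
      raw <- pmax(boxcox_inverse(y, config$transform), 1e-9)
    }
    ipd_table(data.frame(ref_name = latent$ref_name[idx],
                         position = latent$position[idx],
                         strand = latent$strand[idx],
                         movie_id = movie, ipd = raw,
                         stringsAsFactors = FALSE),
              chemistry_tag = "sim", scale = "raw")
  }
  native <- draw_table("nat", config$coverage_native, latent$deviation,
                       shift)
  control <- draw_table("ctl", config$coverage_control, latent$deviation,
                        numeric(nrow(latent)))
  dev_hist <- rnorm(nrow(latent), 0, config$position_noise_sd)
  historical <- draw_table("his", config$coverage_historical, dev_hist,
                           numeric(nrow(latent)))
  structure(list(genome = genome, native = native, control = control,
                 historical = historical, truth = truth, latent = latent,
                 weights = w, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> genome %d bp, %d modified site(s); native %d / control %d / historical %d observations\n",
              sum(nchar(x$genome)), nrow(x$truth), nrow(x$native),
              nrow(x$control), nrow(x$historical)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, three `#kinemod_ipd_v1` TSVs, a BED6 truth file and a JSON
#' parameter log.
#'
#' @param sim a [simulate_dataset()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of paths written
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             native = file.path(dir, "native.tsv"),
             control = file.path(dir, "control.tsv"),
             historical = file.path(dir, "historical.tsv"),
             truth = file.path(dir, "truth.bed"),
             params = file.path(dir, "params.json"))
  write_reference(sim$genome, paths[["fasta"]])
  write_ipd_table(sim$native, paths[["native"]])
  write_ipd_table(sim$control, paths[["control"]])
  write_ipd_table(sim$historical, paths[["historical"]])
  write_truth_bed(sim$truth, paths[["truth"]])
  cfg <- sim$config
  cfg$window <- unclass(cfg$window)
  cfg$transform <- unclass(cfg$transform)
  jsonlite::write_json(unclass(cfg), paths[["params"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

# genome with an exact count of forward-strand motif occurrences: plant at
# evenly spaced slots, then mutate away any surplus matches
.genome_with_motif_count <- function(len, motif, count) {
  bases <- c("A", "C", "G", "T")
  g <- paste(sample(bases, len, replace = TRUE), collapse = "")
  slots <- round(seq(10L, len - nchar(motif) - 10L, length.out = count))
  for (it in 1:50) {
    for (s in slots) substr(g, s + 1L, s + nchar(motif)) <- motif
    occ <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(motif), Biostrings::DNAString(g))) - 1L
    extra <- setdiff(occ, slots)
    if (!length(extra) && length(occ) == count) break
    for (e in extra) {
      j <- e + 2L  # mutate the surplus match's third base
      substr(g, j + 1L, j + 1L) <-
        sample(setdiff(bases, substr(g, j + 1L, j + 1L)), 1L)
    }
  }
  list(genome = c(plasmid = g), sites = sort(slots))
}

#' Plasmid evaluation fixtures
#'
#' Desk-scale stand-ins (synthetic) for the two engineered-plasmid
#' evaluation substrates: a ~3.6 kb plasmid methylated at every GATC
#' occurrence. The `strong_signal_6mA_like` kind plants 23 N6-methyladenine
#' sites (6-mA shifts kinetics strongly: delta = 2 read-noise SDs, with a
#' half-amplitude footprint 4 bases downstream); the `weak_signal_4mC_like`
#' kind plants 19 N4-methylcytosine sites (delta = 0.8 read-noise SDs, no
#' footprint). Modified bases sit on the forward strand (the adenine at
#' GATC offset 1, the cytosine at offset 3). The generative and analysis
#' context window is `(2, 1)`, small enough that every context recurs often
#' in a plasmid-sized genome. Seeds are fixed per kind.
#'
#' @param kind `"strong_signal_6mA_like"` or `"weak_signal_4mC_like"`
#' @param ... overrides passed to [sim_config()] (e.g. coverages,
#'   `mod_proportion`, `genome_length`, `seed`)
#' @return a [simulate_dataset()] result
#' @export
plasmid_fixture <- function(kind = c("strong_signal_6mA_like",
                                     "weak_signal_4mC_like"), ...) {
  kind <- match.arg(kind)
  strong <- kind == "strong_signal_6mA_like"
  over <- list(...)
  seed <- over$seed %||% if (strong) 2013L else 1987L
  glen <- over$genome_length %||% if (strong) 3591L else 3589L
  n_sites <- if (strong) 23L else 19L
  read_sd <- over$read_noise_sd %||% 0.5
  set.seed(seed)
  gm <- .genome_with_motif_count(glen, "GATC", n_sites)
  moff <- if (strong) 1L else 3L   # A of GATC vs C of GATC
  sites <- data.frame(ref_name = "plasmid", position = gm$sites + moff,
                      strand = "+", stringsAsFactors = FALSE)
  modification <- list(
    sites = sites,
    delta = if (strong) 2.0 * read_sd else 0.8 * read_sd,
    footprint = if (strong) list(list(offset = 4L, rel = 0.5)) else list())
  args <- list(genome = gm$genome, window = context_window(2L, 1L),
               modification = modification, seed = seed,
               read_noise_sd = read_sd)
  keep <- setdiff(names(over),
                  c("seed", "genome_length", "read_noise_sd", names(args)))
  cfg <- do.call(sim_config, c(args, over[keep]))
  simulate_dataset(cfg)
}

#' Exponential-mode WGA fixture for transform calibration
#'
#' Emulates a whole-genome-amplified dataset in the robustness mode where
#' raw IPDs are exponential with log-mean tied to the latent rate. Movie
#' structure follows the instrument reality of many movies with large
#' overall shifts: 45 movies with log-scale offsets of SD 0.5. At coverage
#' 200 the per-position moment diagnostics of the calibrated transform are
#' stable.
#'
#' @param genome_length genome size (default 350 bp, i.e. 700 strand
#'   positions)
#' @param coverage per-position coverage (default 200)
#' @param seed integer seed
#' @return a [simulate_dataset()] result
#' @export
wga_exponential_fixture <- function(genome_length = 350L, coverage = 200L,
                                    seed = 7L) {
  cfg <- sim_config(genome_length = genome_length,
                    coverage_native = coverage, coverage_control = coverage,
                    coverage_historical = coverage,
                    n_movies = 45L, movie_offset_sd = 0.5,
                    modification = list(sites = data.frame(
                      ref_name = character(), position = integer(),
                      strand = character())),
                    raw_exponential = TRUE, seed = seed)
  simulate_dataset(cfg)
}
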