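#' Configuration for the synthetic successional-community generator
#'
#' Defaults emulate a single-site seasonal survey of a host diversity panel:
#' 60 genotypes from 3 genetic subpopulations (plus admixed individuals)
#' sampled at 5 timepoints, directional community turnover, a
#' subpopulation displacement that grows linearly through the season, one
#' causal SNP shifting a small set of target OTUs, guild-structured
#' covariance with the pathogen guild carrying the dominant temporal
#' loadings, per-timepoint negative controls carrying contaminant OTUs, and
#' a paired infected leaf for a fraction of genotypes late in the season.
#'
#' @param n_genotypes number of host genotypes (subjects), default 60.
#' @param n_timepoints number of sampling dates, default 5.
#' @param n_subpops number of genetic subpopulations, default 3.
#' @param admix_fraction fraction of admixed individuals, default 0.1.
#' @param n_otus number of real (non-contaminant) OTUs, default 100.
#' @param n_snps number of biallelic SNPs, default 500.
#' @param fst Balding-Nichols differentiation parameter in (0,1),
#'   default 0.3.
#' @param depth_mean expected reads per sample, default 5000.
#' @param time_shift per-step displacement magnitude of the community
#'   centroid in latent log-abundance space, default 0.6.
#' @param subpop_effect late-season subpopulation displacement magnitude,
#'   default 1.5.
#' @param causal_snp_effect per-dosage latent log-abundance shift on the
#'   target OTUs, default 0.8.
#' @param n_target_otus number of OTUs responding to the causal SNP,
#'   default 5.
#' @param guild_block_corr within-guild latent noise correlation in
#'   \[-1, 1\], default 0.5.
#' @param contam_n number of contaminant OTUs (control-exclusive),
#'   default 5.
#' @param n_drivers number of pathogen-guild OTUs with dominant temporal
#'   loadings, default 8.
#' @param host_effect polygenic host effect magnitude on the latent host
#'   axis, default 1.
#' @param infect_fraction fraction of genotypes contributing an extra
#'   infected leaf at the last two timepoints, default 0.2.
#' @param infect_effect latent shift of infected leaves along the infection
#'   direction, default 0.8.
#' @param noise_sd latent noise standard deviation, default 1.
#' @param n_controls_per_tp negative controls per timepoint, default 2.
#' @param seed integer seed; required when simulating.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 60, n_timepoints = 5, n_subpops = 3,
                       admix_fraction = 0.1, n_otus = 100, n_snps = 500,
                       fst = 0.3, depth_mean = 5000, time_shift = 0.8,
                       subpop_effect = 1.5, causal_snp_effect = 0.8,
                       n_target_otus = 5, guild_block_corr = 0.5,
                       contam_n = 5, n_drivers = 8, host_effect = 1,
                       infect_fraction = 0.2, infect_effect = 0.8,
                       noise_sd = 0.5, n_controls_per_tp = 2, seed = NULL) {
  cfg <- as.list(environment())
  counts <- c("n_genotypes", "n_timepoints", "n_otus", "n_snps",
              "n_target_otus", "n_drivers", "n_controls_per_tp")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop_input("%s must be >= 1", nm)
  if (cfg$n_subpops < 2) stop_input("n_subpops must be >= 2")
  if (cfg$fst <= 0 || cfg$fst >= 1) stop_input("fst must lie in (0, 1)")
  for (nm in c("admix_fraction", "infect_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop_input("%s must lie in [0, 1]", nm)
  if (abs(cfg$guild_block_corr) > 1)
    stop_input("guild_block_corr must lie in [-1, 1]")
  if (cfg$contam_n < 0) stop_input("contam_n must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate subpopulation-structured genotypes
#'
#' Balding-Nichols model: each SNP has an ancestral frequency and
#' per-subpopulation frequencies drawn from
#' `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`. Admixed individuals draw alleles
#' from a random mixture of two subpopulation frequency vectors. SNPs are
#' rejection-resampled until the realised minor-allele frequency is at
#' least 0.05.
#'
#' @param config a [sim_config()] with a `seed`.
#' @return a [genotype_matrix()] with attributes `subpopulation` (per
#'   individual; admixed individuals are labelled `"admixed"`) and
#'   `admix_weights`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop_input("config$seed is required")
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_genotypes; m <- config$n_snps; S <- config$n_subpops
  n_admix <- round(config$admix_fraction * n)
  pure <- n - n_admix
  subpop <- c(rep_len(paste0("pop", seq_len(S)), pure),
              rep("admixed", n_admix))
  mix_from <- t(vapply(seq_len(n_admix), function(i)
    sample.int(S, 2), integer(2)))
  mix_w <- runif(n_admix, 0.25, 0.75)
  fst <- config$fst
  a_scale <- (1 - fst) / fst
  G <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    repeat {
      p0 <- runif(1, 0.1, 0.9)
      ps <- rbeta(S, p0 * a_scale, (1 - p0) * a_scale)
      ps <- pmin(pmax(ps, 1e-4), 1 - 1e-4)
      pi_ind <- numeric(n)
      pi_ind[seq_len(pure)] <- ps[match(subpop[seq_len(pure)],
                                        paste0("pop", seq_len(S)))]
      if (n_admix)
        pi_ind[pure + seq_len(n_admix)] <-
          mix_w * ps[mix_from[, 1]] + (1 - mix_w) * ps[mix_from[, 2]]
      g <- rbinom(n, 2, pi_ind)
      maf <- min(mean(g) / 2, 1 - mean(g) / 2)
      if (maf >= 0.05) break
    }
    G[, j] <- g
  }
  rownames(G) <- sprintf("G%03d", seq_len(n))
  colnames(G) <- sprintf("snp%04d", seq_len(m))
  gm <- genotype_matrix(G, data.frame(snp = colnames(G), chrom = "chr1",
                                      pos = seq_len(m)),
                        maf_min = 0.05, miss_max = 1)
  attr(gm, "subpopulation") <- setNames(subpop, rownames(G))
  attr(gm, "admix_weights") <- mix_w
  gm
}

# block-correlated guild noise: one shared factor per guild block
guild_noise <- function(n, guilds, rho, sd) {
  blocks <- unique(guilds)
  eps <- matrix(rnorm(n * length(guilds)), n, length(guilds))
  if (rho != 0) {
    f <- matrix(rnorm(n * length(blocks)), n, length(blocks))
    colnames(f) <- blocks
    eps <- sqrt(abs(rho)) * sign(rho) * f[, guilds, drop = FALSE] +
      sqrt(1 - abs(rho)) * eps
  }
  eps * sd
}

#' Simulate a successional OTU table with known ground truth
#'
#' Latent per-sample OTU log-abundances combine an OTU baseline, a
#' directional temporal loading, a subpopulation displacement growing
#' linearly with timepoint, a polygenic host axis, a causal-SNP shift on
#' target OTUs and guild-block correlated noise; counts are multinomial
#' draws at Poisson read depths (compositional closure). Negative controls
#' carry the contaminant OTUs plus sparse low-depth carryover of the real
#' community. Every planted signal is recorded in the ground-truth object.
#'
#' @param config a [sim_config()] with a `seed`.
#' @param genotypes a [simulate_genotypes()] result for the same config.
#' @return list with `table` (an [otu_table()]) and `truth` (class
#'   `ground_truth`): `causal_snp_index`, `target_otu_ids`,
#'   `contaminant_otu_ids`, `driver_otu_ids`, `centroids` (per
#'   subpopulation x timepoint latent centroids on the driver axis),
#'   `true_h2`, `latent` (samples x OTUs), `host_axis`, `seed`.
#' @export
simulate_succession <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  if (nrow(genotypes$dosages) != config$n_genotypes)
    stop_input("genotype panel does not match config (%d vs %d individuals)",
               nrow(genotypes$dosages), config$n_genotypes)
  set.seed(stage_seed(config$seed, "succession"))
  p <- config$n_otus; Tn <- config$n_timepoints
  subpop <- attr(genotypes, "subpopulation")
  genos <- rownames(genotypes$dosages)

  guild_pool <- c("pathogen", "yeast", "mycoparasite", "saprotroph", "other")
  guild_share <- c(0.15, 0.15, 0.10, 0.30, 0.30)
  guilds <- rep(guild_pool, times = round(guild_share * p))[seq_len(p)]
  guilds[is.na(guilds)] <- "other"
  otu_ids <- sprintf("OTU_%03d", seq_len(p))
  classes <- c(pathogen = "Dothideomycetes", yeast = "Tremellomycetes",
               mycoparasite = "Sordariomycetes",
               saprotroph = "Leotiomycetes", other = "Eurotiomycetes")

  base <- rnorm(p, 0, 1.25)
  # pathogen guild receives the dominant temporal loadings (planted drivers)
  path_idx <- which(guilds == "pathogen")
  drivers <- path_idx[seq_len(min(config$n_drivers, length(path_idx)))]
  # temporal loadings live on the drivers alone, so the recorded ground
  # truth is exactly the set of temporally structured taxa; alternating
  # signs give early-season decliners and late-season bloomers and keep the
  # total community mass stable through the season
  timeload <- numeric(p)
  timeload[drivers] <- rep(c(-1, 1), length.out = length(drivers)) *
    runif(length(drivers), 0.8, 1.2)
  # succession drivers are dominant community members: late-season pathogen
  # blooms in phyllosphere communities come from the most abundant taxa
  base[drivers] <- abs(base[drivers]) + 1.25

  # target OTUs for the causal SNP: yeasts, disjoint from drivers
  yeast_idx <- setdiff(which(guilds == "yeast"), drivers)
  targets <- yeast_idx[seq_len(min(config$n_target_otus, length(yeast_idx)))]
  maf <- pmin(genotypes$freq, 1 - genotypes$freq)
  causal <- which(maf >= 0.2 & maf <= 0.45)
  causal <- if (length(causal)) causal[ceiling(length(causal) / 2)] else
    which.max(maf)
  dosage <- genotypes$dosages[, causal]

  # subpopulation displacement directions (unit vectors), linear in time;
  # supported on a sparse set of prevalent non-driver taxa so the
  # host-genetic signal is visible to Bray-Curtis, does not ride on the
  # succession drivers, and leaves most taxa free of planted structure
  abund_w <- sqrt(exp(base) / sum(exp(base)))
  abund_w[drivers] <- 0
  pops <- paste0("pop", seq_len(config$n_subpops))
  disp <- lapply(pops, function(s) {
    v <- rnorm(p) * abund_w
    v / sqrt(sum(v^2))
  })
  names(disp) <- pops

  # polygenic latent host axis from all SNPs
  Z <- scale(genotypes$dosages)
  Z[is.na(Z)] <- 0
  u <- as.vector(Z %*% rnorm(ncol(Z), 0, 1 / sqrt(ncol(Z))))
  u <- (u - mean(u)) / sd(u)
  names(u) <- genos
  host_dir <- rnorm(p) * abund_w
  host_dir <- host_dir / sqrt(sum(host_dir^2))

  infect_dir <- numeric(p)
  infect_dir[path_idx] <- abs(rnorm(length(path_idx)))
  infect_dir <- infect_dir / sqrt(sum(infect_dir^2))

  infected_genos <- genos[seq_len(round(config$infect_fraction *
                                          length(genos)))]

  # assemble the sample sheet
  rows <- list()
  for (tp in seq_len(Tn)) {
    for (gi in seq_along(genos)) {
      rows[[length(rows) + 1]] <- data.frame(
        genotype = genos[gi], timepoint = tp, infected = FALSE,
        is_control = FALSE)
      if (genos[gi] %in% infected_genos && tp >= Tn - 1)
        rows[[length(rows) + 1]] <- data.frame(
          genotype = genos[gi], timepoint = tp, infected = TRUE,
          is_control = FALSE)
    }
    for (ci in seq_len(config$n_controls_per_tp))
      rows[[length(rows) + 1]] <- data.frame(
        genotype = sprintf("control_%d_%d", tp, ci), timepoint = tp,
        infected = FALSE, is_control = TRUE)
  }
  meta <- do.call(rbind, rows)
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  meta$subpopulation <- ifelse(meta$is_control, "control",
                               subpop[meta$genotype])
  meta$site <- "focal"
  meta$doy <- 160 + 25 * (meta$timepoint - 1)

  real <- !meta$is_control
  nr <- sum(real)
  lat <- matrix(rep(base, each = nr), nr, p)
  tp_real <- meta$timepoint[real]
  lat <- lat + outer(tp_real - 1, timeload) * config$time_shift
  frac <- (tp_real - 1) / (Tn - 1)
  sp_real <- meta$subpopulation[real]
  for (s in pops) {
    idx <- sp_real == s
    lat[idx, ] <- lat[idx, ] + config$subpop_effect *
      outer(frac[idx], disp[[s]])
  }
  adm <- which(sp_real == "admixed")
  if (length(adm)) {
    # admixed hosts: average of all subpopulation directions
    avg_dir <- Reduce(`+`, disp) / length(disp)
    lat[adm, ] <- lat[adm, ] + config$subpop_effect *
      outer(frac[adm], avg_dir)
  }
  dos_real <- dosage[meta$genotype[real]]
  lat[, targets] <- lat[, targets] + config$causal_snp_effect *
    matrix(dos_real, nr, length(targets))
  # polygenic host control strengthens through the season, like the
  # subpopulation displacement
  lat <- lat + config$host_effect *
    outer(frac * u[meta$genotype[real]], host_dir)
  if (any(meta$infected[real]))
    lat[meta$infected[real], ] <- lat[meta$infected[real], , drop = FALSE] +
      config$infect_effect * matrix(infect_dir, sum(meta$infected[real]), p,
                                    byrow = TRUE)
  noise <- guild_noise(nr, guilds, config$guild_block_corr, config$noise_sd)
  lat_noisy <- lat + noise

  # realised heritability of the latent host axis (projection on host_dir)
  # at the final timepoint, where host control is fully expressed
  last <- tp_real == Tn
  sig <- config$host_effect * u[meta$genotype[real]][last]
  prj <- as.vector(noise[last, , drop = FALSE] %*% host_dir)
  true_h2 <- var(sig) / (var(sig) + var(prj))

  # counts: multinomial at Poisson depth over softmax proportions;
  # contaminant OTUs are appended, control-exclusive
  n_contam <- config$contam_n
  contam_ids <- if (n_contam) sprintf("CONTAM_%02d", seq_len(n_contam))
                else character()
  all_ids <- c(otu_ids, contam_ids)
  counts <- matrix(0L, nrow(meta), length(all_ids),
                   dimnames = list(meta$sample_id, all_ids))
  depth <- rpois(nrow(meta), config$depth_mean)
  depth[meta$is_control] <- rpois(sum(meta$is_control),
                                  config$depth_mean / 10)
  depth <- pmax(depth, 10)
  prop_real <- exp(lat_noisy - apply(lat_noisy, 1, max))
  prop_real <- prop_real / rowSums(prop_real)
  ridx <- which(real)
  for (i in seq_along(ridx))
    counts[ridx[i], seq_len(p)] <-
      as.integer(rmultinom(1, depth[ridx[i]], prop_real[i, ]))
  mean_comm <- colMeans(prop_real)
  contam_base <- if (n_contam) exp(rnorm(n_contam, 0, 0.5)) else numeric()
  for (i in which(meta$is_control)) {
    pr <- if (n_contam)
      c(0.05 * mean_comm, 0.95 * contam_base / sum(contam_base))
    else mean_comm
    # one guaranteed read per contaminant keeps control prevalence at 1
    # while preserving the drawn depth exactly
    counts[i, ] <- as.integer(rmultinom(1, depth[i] - n_contam, pr))
    if (n_contam)
      counts[i, p + seq_len(n_contam)] <-
        counts[i, p + seq_len(n_contam)] + 1L
  }

  otu_meta <- data.frame(
    otu_id = all_ids,
    class = c(classes[guilds], rep("Unknown", n_contam)),
    guild = c(guilds, rep("contaminant", n_contam)))
  tab <- otu_table(counts, meta, otu_meta)

  centroids <- lapply(pops, function(s) {
    vapply(seq_len(Tn), function(tp) {
      idx <- real & meta$subpopulation == s & meta$timepoint == tp
      mean(lat[idx[real], , drop = FALSE] %*% timeload /
             sqrt(sum(timeload^2)))
    }, 0)
  })
  names(centroids) <- pops

  truth <- structure(list(
    causal_snp_index = unname(causal),
    causal_snp_id = colnames(genotypes$dosages)[causal],
    target_otu_ids = otu_ids[targets],
    contaminant_otu_ids = contam_ids,
    driver_otu_ids = otu_ids[drivers],
    centroids = centroids,
    true_h2 = unname(true_h2),
    host_axis = u,
    latent = `dimnames<-`(lat, list(meta$sample_id[real], otu_ids)),
    seed = config$seed), class = "ground_truth")
  list(table = tab, truth = truth)
}

#' Write / read a ground-truth record as JSON
#'
#' @param truth a `ground_truth` from [simulate_succession()].
#' @param path JSON output path.
#' @return `truth_report` returns `path` invisibly; `read_truth` returns the
#'   scalar/vector fields of the record (the latent matrix is not
#'   serialised).
#' @export
truth_report <- function(truth, path) {
  rec <- list(seed = truth$seed,
              causal_snp_index = truth$causal_snp_index,
              causal_snp_id = truth$causal_snp_id,
              target_otu_ids = as.list(truth$target_otu_ids),
              contaminant_otu_ids = as.list(truth$contaminant_otu_ids),
              driver_otu_ids = as.list(truth$driver_otu_ids),
              true_h2 = truth$true_h2)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname truth_report
#' @export
read_truth <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("target_otu_ids", "contaminant_otu_ids", "driver_otu_ids"))
    rec[[nm]] <- as.character(unlist(rec[[nm]]))
  rec
}

#' One-call simulation of genotypes plus community table
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `table`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config(seed = 1)) {
  g <- simulate_genotypes(config)
  s <- simulate_succession(config, g)
  list(genotypes = g, table = s$table, truth = s$truth)
}
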