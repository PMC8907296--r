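#' Simulate per-cell vector integration counts
#'
#' Each cell absorbs a Poisson(MOI) number of vector particles, so the
#' integration count per cell is i.i.d. Poisson with rate `moi`; the fraction
#' of untransduced cells is `exp(-moi)`.
#'
#' @param nCells number of target cells.
#' @param moi multiplicity of infection (mean particles per cell, >= 0).
#' @param seed RNG seed.
#' @return integer vector of per-cell integration counts.
#' @export
simulateTransduction <- function(nCells, moi, seed = NULL) {
  if (moi < 0) stop("moi must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rpois(nCells, moi)
}

#' Simulate a transduced clone pool
#'
#' Transduces `nCells` cells at the given MOI, expands each transduced cell
#' into a clone with a random size (log-normal by default, giving realistic
#' clonal dominance; uniform for maximal-entropy checks), and assigns every
#' integration a unique IS label. Integrations in the same cell share the
#' clone's size.
#'
#' @param nCells number of cells exposed to vector.
#' @param moi multiplicity of infection.
#' @param law `"lognormal"` or `"uniform"` clone-size law.
#' @param sdlog log-scale SD of the log-normal clone sizes.
#' @param seed RNG seed.
#' @return list: `freq` (named IS relative abundances), `vcn` (mean
#'   integrations per cell over all cells), `nClones`, `entropy` (true pool
#'   entropy).
#' @export
simulateClonePool <- function(nCells = 3000L, moi = 1, law = "lognormal",
                              sdlog = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ints <- simulateTransduction(nCells, moi)
  transduced <- which(ints > 0L)
  if (!length(transduced)) stop("no transduced cells at this MOI; increase nCells")
  sizes <- switch(law,
    lognormal = rlnorm(length(transduced), 0, sdlog),
    uniform = rep(1, length(transduced)),
    stop("unknown clone abundance law: ", law))
  ab <- rep(sizes, ints[transduced])
  names(ab) <- sprintf("chr%d:%d:%s",
                       sample(1:19, length(ab), replace = TRUE),
                       sample.int(1.2e8, length(ab)),
                       sample(c("+", "-"), length(ab), replace = TRUE))
  list(freq = ab / sum(ab), vcn = mean(ints), nClones = length(transduced),
       entropy = shannonEntropy(ab))
}

#' Simulate one IS library from a clone pool
#'
#' Two-stage detection model reproducing the confounding mechanics: (1) a DNA
#' aliquot samples `round(dna_ng * genomePerNg)` genomes from the pool
#' (multinomial over the true clone frequencies); (2) sequencing draws
#' `depth` reads (multinomial over the sampled-genome IS frequencies).
#' Shallow libraries and small aliquots miss rare clones, so the observed
#' entropy increases with both DNA amount and depth and saturates at the true
#' pool entropy.
#'
#' @param pool result of [simulateClonePool()].
#' @param dna_ng DNA amount in nanograms.
#' @param depth number of sequencing reads.
#' @param genomePerNg genomes sampled per ng of DNA (default 152: a diploid
#'   mammalian genome weighs about 6.6 pg).
#' @param seed RNG seed.
#' @param sample_id sample identifier.
#' @return abundance-sample list: `sample_id`, `abundances` (named read
#'   counts of detected IS), `dna_ng`, `vcn`, `sd`.
#' @export
simulateISSample <- function(pool, dna_ng, depth, genomePerNg = 152,
                             seed = NULL, sample_id = "S1") {
  if (dna_ng <= 0 || depth <= 0) stop("dna_ng and depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  genomes <- max(1L, round(dna_ng * genomePerNg))
  gcnt <- as.vector(rmultinom(1L, genomes, pool$freq))
  if (sum(gcnt) == 0L) stop("empty sampled pool")
  reads <- as.vector(rmultinom(1L, round(depth), gcnt))
  keep <- reads > 0L
  list(sample_id = sample_id,
       abundances = setNames(reads[keep], names(pool$freq)[keep]),
       dna_ng = dna_ng, vcn = pool$vcn, sd = as.integer(round(depth)))
}

#' Simulate an in-vitro IS assay
#'
#' Emulates the validation-assay design: one cell line transduced at several
#' MOIs (yielding distinct VCN levels and polyclonality), IS libraries
#' prepared from several DNA amounts with technical replicates, and a
#' sequencing depth that scales with the input DNA and IS content (library
#' yield grows with template) times log-normal pooling noise -- so DNA, VCN
#' and SD all confound the observed entropy.
#'
#' @param moiLevels,dnaLevels,replicates design grid.
#' @param nCells cells per transduction arm.
#' @param baseDepth median read depth at the reference condition.
#' @param seed RNG seed (fully determines the dataset).
#' @return an [ISAbundanceExperiment-class] with colData columns `dna_ng`,
#'   `vcn`, `sd`.
#' @export
simulateInVitroAssay <- function(moiLevels = c(0.1, 1, 10),
                                 dnaLevels = c(5, 20, 100),
                                 replicates = 3L, nCells = 3000L,
                                 baseDepth = 3000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- list()
  for (m in moiLevels) {
    pool <- simulateClonePool(nCells, m)
    for (d in dnaLevels) for (r in seq_len(replicates)) {
      depth <- max(200, round(baseDepth * (d / 20)^0.6 *
                                max(pool$vcn, 0.05)^0.4 * rlnorm(1, 0, 0.4)))
      id <- sprintf("moi%g_dna%g_r%d", m, d, r)
      samples[[id]] <- simulateISSample(pool, d, depth, sample_id = id)
    }
  }
  isIds <- unique(unlist(lapply(samples, function(s) names(s$abundances))))
  cnt <- matrix(0, length(isIds), length(samples),
                dimnames = list(isIds, names(samples)))
  for (j in seq_along(samples))
    cnt[names(samples[[j]]$abundances), j] <- samples[[j]]$abundances
  meta <- data.frame(
    dna_ng = vapply(samples, `[[`, 0, "dna_ng"),
    vcn = vapply(samples, `[[`, 0, "vcn"),
    sd = vapply(samples, `[[`, 0L, "sd"),
    row.names = names(samples))
  ISAbundanceExperiment(cnt, meta)
}

.michaelisMenten <- function(a, b) {
  force(a); force(b)
  function(x) a * x / (b + x)
}

#' Default Michaelis-Menten confounder effects
#'
#' Scaled saturation curves `a x / (b + x)`: monotone increasing, concave and
#' saturating, i.e. exactly the shape hypothesis the model encodes.
#' @keywords internal
.defaultConfounders <- function() list(
  dna_ng = list(range = c(5, 100), effect = .michaelisMenten(0.6, 20)),
  vcn = list(range = c(0.2, 10), effect = .michaelisMenten(0.4, 2)),
  sd = list(range = c(600, 50000), effect = .michaelisMenten(0.8, 5000)))

#' Simulate an entropy table directly from the log-linear model
#'
#' Draws confounder values uniformly on their ranges and generates
#' `log(h) = beta0 + sum_k m_k(x_k) + eps`, `eps ~ N(0, sigma^2)`, with known
#' monotone/concave/saturating effect functions, so recovery and
#' confounder-removal behaviour can be tested against ground truth.
#'
#' @param n number of samples.
#' @param confounders named list; each element has `range` (length 2) and
#'   `effect` (a function). Defaults to three Michaelis-Menten effects for
#'   `dna_ng`, `vcn` and `sd`.
#' @param beta0 baseline log-entropy.
#' @param sigma noise SD on the log scale.
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, `h`, `log_h` and one column per
#'   confounder; attribute `truth` holds `beta0`, `sigma` and the effect
#'   functions.
#' @export
simulateEntropyDataset <- function(n = 200L, confounders = .defaultConfounders(),
                                   beta0 = 1.2, sigma = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  et <- data.frame(sample_id = sprintf("S%03d", seq_len(n)))
  logh <- rep(beta0, n)
  for (nm in names(confounders)) {
    cf <- confounders[[nm]]
    x <- runif(n, cf$range[1], cf$range[2])
    et[[nm]] <- x
    logh <- logh + cf$effect(x)
  }
  logh <- logh + rnorm(n, 0, sigma)
  et$h <- exp(logh)
  et$log_h <- logh
  et <- et[, c("sample_id", "h", "log_h", names(confounders))]
  attr(et, "truth") <- list(beta0 = beta0, sigma = sigma,
                            effects = lapply(confounders, `[[`, "effect"))
  et
}

#' Simulate a longitudinal mouse genotoxicity study
#'
#' Pools of mice per vector arm are bled at monthly time points; mice in the
#' genotoxic arm die earlier, so the pool size (PS) is nonincreasing over
#' time and sampling stops when a pool is exhausted. True log-entropies
#' follow the model: a per-lineage baseline, a monotone-decreasing
#' lineage-by-vector decay that levels off at late times (steeper for the
#' genotoxic vector except in the B compartment), plus saturating confounder
#' effects of DNA, VCN, PS and SD, plus Gaussian noise.
#'
#' @param nPoolsPerArm pools per vector arm.
#' @param lineages,vectors factor levels; `vectors[2]` is the genotoxic arm.
#' @param times sampling time points (months).
#' @param beta0 baseline log-entropy.
#' @param sigma noise SD on the log scale.
#' @param seed RNG seed.
#' @return entropy table (`sample_id`, `h`, `log_h`, `dna_ng`, `vcn`, `sd`,
#'   `ps`, `time`, `lineage`, `vector`, `pool`); attribute `truth` holds the
#'   decay functions (named `decay.<lineage>.<vector>`) and effect functions.
#' @export
simulateMouseDesign <- function(nPoolsPerArm = 4L,
                                lineages = c("MNC", "T", "B", "Myeloid"),
                                vectors = c("PGK", "LTR"),
                                times = 1:10, beta0 = 1.6, sigma = 0.1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eff <- list(dna_ng = .michaelisMenten(0.35, 100),
              vcn = .michaelisMenten(0.3, 4),
              ps = .michaelisMenten(0.5, 2),
              sd = .michaelisMenten(0.5, 8000))
  decayAmp <- function(l, v) {
    if (v == vectors[2]) { if (l == "B") 0.3 else 0.9 } else 0.2
  }
  decays <- list()
  rows <- list()
  for (v in vectors) for (pl in seq_len(nPoolsPerArm)) {
    nMice <- sample(2:3, 1L)
    deathT <- if (v == vectors[2]) runif(nMice, 0.4, 0.8) * max(times)
              else runif(nMice, 0.7, 1.3) * max(times)
    for (tm in times) {
      ps <- sum(deathT >= tm)
      if (ps == 0L) break
      for (l in lineages) {
        lab <- paste0("decay.", l, ".", v)
        if (is.null(decays[[lab]])) {
          amp <- decayAmp(l, v)
          decays[[lab]] <- local({
            a <- amp
            function(t) -a * (1 - exp(-t / 3))
          })
        }
        dna <- ps * runif(1, 40, 160)
        vcn <- rlnorm(1, log(if (v == vectors[1]) 12 else 6), 0.3)
        sdv <- round(exp(runif(1, log(1000), log(80000))))
        lbase <- beta0 + 0.1 * (match(l, lineages) - 1)
        logh <- lbase + decays[[lab]](tm) + eff$dna_ng(dna) + eff$vcn(vcn) +
          eff$ps(ps) + eff$sd(sdv) + rnorm(1, 0, sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_p%d_%s_t%02d", v, pl, l, tm),
          h = exp(logh), log_h = logh, dna_ng = dna, vcn = vcn,
          sd = sdv, ps = ps, time = tm, lineage = l, vector = v,
          pool = sprintf("%s_p%d", v, pl), stringsAsFactors = FALSE)
      }
    }
  }
  et <- do.call(rbind, rows)
  rownames(et) <- NULL
  attr(et, "truth") <- list(beta0 = beta0, sigma = sigma, decays = decays,
                            effects = eff)
  et
}
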