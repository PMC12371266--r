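#' Synthetic-world configuration
#'
#' One seeded configuration drives every synthetic object: a chromosome of
#' alternating early/late replication domains, uniformly placed enhancer and
#' promoter elements, loops whose presence is coupled to the local RT
#' pattern, and multi-sample two-group cohorts with planted group-specific
#' perturbations.
#'
#' Domain lengths are exponential with a ~1 Mb overall mean, split
#' asymmetrically (early 0.2 Mb, late 1.8 Mb) so early/A-compartment-like
#' territory is a genome minority, as in real RT tracks where active
#' compartments are the smaller fraction. Loop coupling multiplies the odds
#' of a candidate pair by `loop_coupling_strength^concordance`;
#' `concordance_mode = "both_early"` (default) credits pairs whose two
#' element flanks both sit in early domains (active-compartment pairing),
#' `"same_phase"` credits any matching phase including late-late.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param bin_size RT profile step in bp.
#' @param early_domain_mean,late_domain_mean exponential mean domain lengths.
#' @param rt_early_mean,rt_late_mean domain-level RT log-ratio means
#'   (early > late required).
#' @param domain_value_sd between-domain RT value spread.
#' @param rt_noise_sd per-bin measurement noise.
#' @param n_enhancers,n_promoters element counts.
#' @param element_length element width in bp.
#' @param min_distance,max_distance candidate pair distance bounds.
#' @param loop_coupling_strength odds multiplier (>= 1; 1 = no coupling).
#' @param concordance_mode `"both_early"` or `"same_phase"`.
#' @param n_loops loops drawn.
#' @param anchor_pad padding added around an element to form its loop anchor.
#' @param flank half-width of the element flank used for the phase call.
#' @param n_samples_per_group cohort samples per group.
#' @param group_shift_sd per-sample per-bin Gaussian jitter.
#' @param n_planted_specific planted group-specific EPIs in cohorts.
#' @param flip_halfwidth half-width of the RT phase flip around a planted
#'   promoter.
#' @param seed integer seed; fully determines all outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom = "chrS", chrom_length = 1e8, bin_size = 1000,
                       early_domain_mean = 2e5, late_domain_mean = 1.8e6,
                       rt_early_mean = 1.5, rt_late_mean = -1.5,
                       domain_value_sd = 0.3, rt_noise_sd = 0.25,
                       n_enhancers = 1100, n_promoters = 850,
                       element_length = 1000,
                       min_distance = 5e3, max_distance = 2e6,
                       loop_coupling_strength = 1000,
                       concordance_mode = c("both_early", "same_phase"),
                       n_loops = 500, anchor_pad = 2500, flank = 5e3,
                       n_samples_per_group = 5, group_shift_sd = 0.1,
                       n_planted_specific = 10, flip_halfwidth = 25e3,
                       seed = 1) {
  stopifnot(chrom_length > 0, bin_size > 0, element_length > 0,
            rt_early_mean > rt_late_mean, loop_coupling_strength >= 0,
            n_loops >= 1)
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 bin_size = bin_size,
                 early_domain_mean = early_domain_mean,
                 late_domain_mean = late_domain_mean,
                 rt_early_mean = rt_early_mean, rt_late_mean = rt_late_mean,
                 domain_value_sd = domain_value_sd, rt_noise_sd = rt_noise_sd,
                 n_enhancers = n_enhancers, n_promoters = n_promoters,
                 element_length = element_length,
                 min_distance = min_distance, max_distance = max_distance,
                 loop_coupling_strength = loop_coupling_strength,
                 concordance_mode = match.arg(concordance_mode),
                 n_loops = n_loops, anchor_pad = anchor_pad, flank = flank,
                 n_samples_per_group = n_samples_per_group,
                 group_shift_sd = group_shift_sd,
                 n_planted_specific = n_planted_specific,
                 flip_halfwidth = flip_halfwidth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# alternating early/late domains covering the chromosome
sim_domains <- function(cfg) {
  lens <- numeric(0)
  early <- logical(0)
  total <- 0
  phase <- runif(1) < 0.5
  while (total < cfg$chrom_length) {
    l <- rexp(1, 1 / (if (phase) cfg$early_domain_mean else cfg$late_domain_mean))
    l <- max(l, 2 * cfg$bin_size)
    lens <- c(lens, l)
    early <- c(early, phase)
    total <- total + l
    phase <- !phase
  }
  ends <- pmin(cumsum(lens), cfg$chrom_length)
  starts <- c(0, ends[-length(ends)])
  keep <- ends > starts
  value <- ifelse(early, rnorm(length(lens), cfg$rt_early_mean, cfg$domain_value_sd),
                  rnorm(length(lens), cfg$rt_late_mean, cfg$domain_value_sd))
  data.table::data.table(start = starts, end = ends, early = early,
                         value = value)[keep]
}

# true domain phase at positions (early = TRUE)
domain_phase_at <- function(domains, pos) {
  domains$early[findInterval(pos, domains$start)]
}

sim_elements <- function(cfg, n) {
  margin <- cfg$element_length
  mid <- sort(runif(n, margin, cfg$chrom_length - margin))
  data.table::data.table(chrom = cfg$chrom,
                         start = round(mid - cfg$element_length / 2),
                         end = round(mid + cfg$element_length / 2))
}

pair_concordance <- function(pairs, domains, cfg) {
  pe <- domain_phase_at(domains, (pairs$enh_start + pairs$enh_end) / 2)
  pp <- domain_phase_at(domains, (pairs$prom_start + pairs$prom_end) / 2)
  if (cfg$concordance_mode == "both_early") as.integer(pe & pp)
  else as.integer(pe == pp)
}

#' Simulate one cell line: RT profile, elements, and coupled loops
#'
#' Alternating early/late RT domains (exponential lengths, Gaussian domain
#' values, per-bin noise); elements placed uniformly; `n_loops` loops drawn
#' without replacement over the candidate enhancer-promoter pairs with
#' probability proportional to `loop_coupling_strength^concordance`.
#' `loop_coupling_strength = 1` makes loops independent of RT (the null
#' world).
#'
#' @param cfg a [sim_config()].
#' @return list with `profile` (an [rt_profile()]), `enhancers`, `promoters`
#'   (element tables), `loops` (BEDPE-style table whose anchors are padded
#'   elements), `truth` (the drawn pair table with its concordance flag),
#'   `candidates` (all candidate pairs with concordance), and `domains`.
#' @export
simulate_cell_line <- function(cfg = sim_config()) {
  local_seed(child_seed(cfg$seed, "cell_line"), {
    domains <- sim_domains(cfg)
    bin_starts <- seq(0, cfg$chrom_length - cfg$bin_size, by = cfg$bin_size)
    bmid <- bin_starts + cfg$bin_size / 2
    dom_idx <- findInterval(bmid, domains$start)
    values <- domains$value[dom_idx] + rnorm(length(bmid), 0, cfg$rt_noise_sd)
    profile <- rt_profile(
      data.table::data.table(chrom = cfg$chrom, start = bin_starts,
                             end = bin_starts + cfg$bin_size, value = values),
      sample_id = "sim_cell_line")
    enhancers <- sim_elements(cfg, cfg$n_enhancers)
    promoters <- sim_elements(cfg, cfg$n_promoters)
    candidates <- enumerate_candidates(enhancers, promoters,
                                       cfg$min_distance, cfg$max_distance)
    if (nrow(candidates) < cfg$n_loops)
      stopf("only %d candidate pairs for %d loops; enlarge the world",
            nrow(candidates), cfg$n_loops)
    conc <- pair_concordance(candidates, domains, cfg)
    w <- cfg$loop_coupling_strength^conc
    pick <- sort(sample(nrow(candidates), cfg$n_loops, prob = w))
    truth <- data.table::copy(candidates)[pick]
    truth$concordant <- conc[pick]
    truth$label <- "positive"
    truth$source <- "simulated_loops"
    loops <- normalize_loops(data.table::data.table(
      chrom = truth$chrom,
      start1 = pmax(0, truth$enh_start - cfg$anchor_pad),
      end1 = truth$enh_end + cfg$anchor_pad,
      start2 = pmax(0, truth$prom_start - cfg$anchor_pad),
      end2 = truth$prom_end + cfg$anchor_pad,
      score = 1))
    candidates$concordant <- conc
    list(profile = profile, enhancers = enhancers, promoters = promoters,
         loops = loops, truth = truth, candidates = candidates,
         domains = domains, config = cfg)
  })
}

#' Simulate a two-group cohort with planted group-specific EPIs
#'
#' Group A samples jitter the base cell line's RT profile; group B samples
#' additionally carry an RT phase flip (sign inversion) in a window around
#' the promoter of each planted EPI, disrupting that interaction in group B
#' only. Planted EPIs are chosen among concordant truth pairs whose flip
#' window does not touch any other EPI's elements, so the planted effect
#' stays local.
#'
#' @param cfg a [sim_config()].
#' @param base optional output of [simulate_cell_line()] (re-simulated from
#'   `cfg` when omitted).
#' @param epis pair table the planting draws from; defaults to `base$truth`.
#' @param group_names two group labels (default `c("A", "B")`; group B is
#'   the perturbed one).
#' @return list with `profiles` (list of per-sample [rt_profile()]s with
#'   group labels), `planted` (pair table of planted A-specific EPIs),
#'   `epis`, and `base`.
#' @export
simulate_cohort <- function(cfg = sim_config(), base = NULL, epis = NULL,
                            group_names = c("A", "B")) {
  if (is.null(base)) base <- simulate_cell_line(cfg)
  if (is.null(epis)) epis <- base$truth
  local_seed(child_seed(cfg$seed, "cohort"), {
    planted <- pick_planted(epis, base, cfg)
    base_bins <- base$profile$chroms[[cfg$chrom]]
    flipped <- data.table::copy(base_bins)
    if (nrow(planted) > 0) {
      pm <- (planted$prom_start + planted$prom_end) / 2
      bmid <- (flipped$start + flipped$end) / 2
      hit <- rep(FALSE, length(bmid))
      for (m in pm)
        hit <- hit | (bmid >= m - cfg$flip_halfwidth &
                        bmid < m + cfg$flip_halfwidth)
      flipped$value[hit] <- -flipped$value[hit]
    }
    make_sample <- function(bins, gname, s) {
      v <- bins$value + rnorm(nrow(bins), 0, cfg$group_shift_sd)
      rt_profile(data.table::data.table(chrom = cfg$chrom, start = bins$start,
                                        end = bins$end, value = v),
                 sample_id = sprintf("%s_%d", gname, s), group = gname)
    }
    profiles <- c(
      lapply(seq_len(cfg$n_samples_per_group),
             function(s) make_sample(base_bins, group_names[1], s)),
      lapply(seq_len(cfg$n_samples_per_group),
             function(s) make_sample(flipped, group_names[2], s)))
    list(profiles = profiles, planted = planted, epis = epis, base = base)
  })
}

# choose planted EPIs: concordant, and isolated so one flip window touches
# no other EPI's elements (shared elements disqualify a pair outright)
pick_planted <- function(epis, base, cfg) {
  if (cfg$n_planted_specific == 0) return(epis[0])
  cand <- data.table::copy(epis)
  if (!"concordant" %in% names(cand))
    cand$concordant <- pair_concordance(cand, base$domains, cfg)
  keep <- cand$concordant == 1
  cand <- cand[keep]
  cand_key <- pair_key(cand)
  epi_key <- pair_key(epis)
  all_pm <- (epis$prom_start + epis$prom_end) / 2
  all_em <- (epis$enh_start + epis$enh_end) / 2
  pm <- (cand$prom_start + cand$prom_end) / 2
  guard <- cfg$flip_halfwidth + 2 * cfg$flank
  ord <- sample(nrow(cand))
  picked <- integer(0)
  for (i in ord) {
    others <- epi_key != cand_key[i]
    # the flip window may touch this EPI's own elements but no other EPI's
    clash <- any((abs(all_pm[others] - pm[i]) < guard) |
                   (abs(all_em[others] - pm[i]) < guard))
    if (clash) next
    if (length(picked) && any(abs(pm[picked] - pm[i]) < 2 * guard)) next
    picked <- c(picked, i)
    if (length(picked) == cfg$n_planted_specific) break
  }
  if (length(picked) < cfg$n_planted_specific)
    warnf("only %d of %d isolated planted EPIs available",
          length(picked), cfg$n_planted_specific)
  cand[sort(picked)]
}

#' Write a simulated world to disk in the package's input formats
#'
#' Emits bedGraph (RT), BED (elements), and BEDPE (loops) files so
#' integration tests exercise the real parsers.
#'
#' @param sim output of [simulate_cell_line()].
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    rt = file.path(dir, "rt.bedgraph"),
    enhancers = file.path(dir, "enhancers.bed"),
    promoters = file.path(dir, "promoters.bed"),
    loops = file.path(dir, "loops.bedpe"))
  write_rt_bedgraph(sim$profile, paths$rt)
  write_bed(sim$enhancers, paths$enhancers)
  write_bed(sim$promoters, paths$promoters)
  write_bedpe(sim$loops, paths$loops)
  paths
}
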