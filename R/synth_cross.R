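#' Parameters for the pooled-segregant cross simulator
#'
#' Describes an F2 mapping cross of whole-genome-homozygous segregants
#' (each clone is homozygous at every site, so pools behave as sets of
#' haploid-derived genotypes), phenotyped and pooled into a mutant and a
#' wildtype pool, then sequenced as pools. One causal variant is planted;
#' linked-marker allele frequencies follow the Haldane map function
#' r = (1 - exp(-2 d c / 100)) / 2 with `d` the physical distance in Mb
#' and `c` the recombination rate in cM/Mb. Unlinked chromosomes
#' segregate at frequency 1/2.
#'
#' @param chromosomes Data frame with columns `name` and `length` (bp).
#' @param marker_spacing Marker grid spacing in bp.
#' @param causal_chrom,causal_pos Location of the planted causal variant
#'   (1-based bp; must lie on `causal_chrom`).
#' @param recomb_rate Recombination rate in cM/Mb.
#' @param pool_size Clones per pool.
#' @param mean_depth Mean per-pool sequencing depth (Poisson).
#' @param phenotyping_error Probability that a clone is assigned to the
#'   wrong pool; must be in \[0, 0.5).
#' @param background_variant_rate Probability that each non-causal
#'   marker-grid site carries a segregating variant (the causal site is
#'   always present).
#' @param impact_probs Named probabilities over
#'   `HIGH, MODERATE, LOW, MODIFIER` used to annotate non-causal sites;
#'   the causal site is always annotated `HIGH`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A validated parameter list of class `"cross_sim_params"`.
#' @seealso [generate_pool_counts()]
#' @export
cross_sim_params <- function(chromosomes = data.frame(
                               name = paste0("chr", 1:5),
                               length = rep(1e7, 5)),
                             marker_spacing = 1e4,
                             causal_chrom = "chr3",
                             causal_pos = 5e6,
                             recomb_rate = 1,
                             pool_size = 32L,
                             mean_depth = 90,
                             phenotyping_error = 0,
                             background_variant_rate = 1,
                             impact_probs = c(HIGH = 5e-4, MODERATE = 4e-3,
                                              LOW = 1.55e-2, MODIFIER = 0.98),
                             seed = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)),
            nrow(chromosomes) >= 1, all(chromosomes$length > 0))
  if (!causal_chrom %in% chromosomes$name) {
    stop("`causal_chrom` is not a listed chromosome", call. = FALSE)
  }
  clen <- chromosomes$length[chromosomes$name == causal_chrom]
  stopifnot_scalar_number(causal_pos, "causal_pos", lower = 1, upper = clen)
  if (marker_spacing > min(chromosomes$length)) {
    stop("`marker_spacing` exceeds a chromosome length", call. = FALSE)
  }
  stopifnot_scalar_number(recomb_rate, "recomb_rate", lower = 0)
  stopifnot_scalar_number(pool_size, "pool_size", lower = 1)
  stopifnot_scalar_number(mean_depth, "mean_depth", lower = 1e-9)
  stopifnot_scalar_number(phenotyping_error, "phenotyping_error", lower = 0)
  if (phenotyping_error >= 0.5) {
    stop("`phenotyping_error` must be < 0.5", call. = FALSE)
  }
  stopifnot_scalar_number(background_variant_rate, "background_variant_rate",
                          lower = 0, upper = 1)
  stopifnot(all(c("HIGH", "MODERATE", "LOW", "MODIFIER") %in%
                  names(impact_probs)),
            all(impact_probs >= 0), sum(impact_probs) > 0)
  structure(list(chromosomes = chromosomes,
                 marker_spacing = marker_spacing,
                 causal_chrom = causal_chrom, causal_pos = causal_pos,
                 recomb_rate = recomb_rate,
                 pool_size = as.integer(pool_size),
                 mean_depth = mean_depth,
                 phenotyping_error = phenotyping_error,
                 background_variant_rate = background_variant_rate,
                 impact_probs = impact_probs / sum(impact_probs),
                 seed = seed),
            class = "cross_sim_params")
}

#' Haldane recombination fraction
#'
#' Converts a physical distance to a recombination fraction assuming no
#' interference: `r = (1 - exp(-2 * d_mb * rate / 100)) / 2`.
#'
#' @param d_bp Distance in bp (vectorized).
#' @param recomb_rate Recombination rate in cM/Mb.
#' @return Recombination fractions in \[0, 0.5).
#' @export
haldane_r <- function(d_bp, recomb_rate) {
  0.5 * (1 - exp(-2 * (d_bp / 1e6) * recomb_rate / 100))
}

#' Simulate pooled variant tables for a two-pool mapping cross
#'
#' Draws each clone's (homozygous) genotype at every marker given its
#' causal-site genotype: on the causal chromosome the clone carries the
#' causal-coupled allele with probability `1 - r` (`r` from
#' [haldane_r()]); elsewhere alleles segregate at 1/2. With probability
#' `phenotyping_error` a clone is placed in the wrong pool. Pool allele
#' frequency is the mean over clones; per-pool depth is
#' Poisson(`mean_depth`) and alt reads are Binomial(depth, frequency).
#'
#' @param params A [cross_sim_params()] object.
#' @return A list with `sites` (data frame: `chrom, pos, ref, alt,
#'   mut_depth, mut_alt, wt_depth, wt_alt, impact`) and `truth` (list:
#'   `causal_chrom`, `causal_pos`, and an `expected` data frame with the
#'   model allele frequencies per pool at every site).
#' @examples
#' ps <- cross_sim_params(chromosomes = data.frame(name = "chrA",
#'                                                 length = 1e6),
#'                        causal_chrom = "chrA", causal_pos = 5e5,
#'                        marker_spacing = 1e5, seed = 7)
#' sim <- generate_pool_counts(ps)
#' head(sim$sites)
#' @export
generate_pool_counts <- function(params) {
  stopifnot(inherits(params, "cross_sim_params"))
  with_seed_opt(params$seed, generate_pool_counts_impl(params))
}

generate_pool_counts_impl <- function(p) {
  marker_list <- lapply(seq_len(nrow(p$chromosomes)), function(i) {
    nm <- p$chromosomes$name[i]
    pos <- seq(p$marker_spacing, p$chromosomes$length[i],
               by = p$marker_spacing)
    if (p$background_variant_rate < 1) {
      pos <- pos[stats::runif(length(pos)) < p$background_variant_rate]
    }
    if (nm == p$causal_chrom) pos <- sort(unique(c(pos, p$causal_pos)))
    data.frame(chrom = rep(nm, length(pos)), pos = pos)
  })
  mk <- do.call(rbind, marker_list)
  m <- nrow(mk)
  if (m == 0L) stop("no marker sites generated", call. = FALSE)

  linked <- mk$chrom == p$causal_chrom
  r <- rep(0.5, m)
  r[linked] <- haldane_r(abs(mk$pos[linked] - p$causal_pos), p$recomb_rate)

  # P(alt) per marker given the clone's causal genotype g in {1, 0};
  # unlinked chromosomes have r = 0.5 so this reduces to 0.5 there
  p_alt_given <- function(g) g * (1 - r) + (1 - g) * r

  sample_pool <- function(target_mut) {
    # causal genotype per clone after phenotyping error
    g <- if (target_mut) {
      as.numeric(stats::runif(p$pool_size) >= p$phenotyping_error)
    } else {
      as.numeric(stats::runif(p$pool_size) < p$phenotyping_error)
    }
    freq <- numeric(m)
    for (k in seq_len(p$pool_size)) {
      freq <- freq + (stats::runif(m) < p_alt_given(g[k]))
    }
    freq / p$pool_size
  }
  mut_freq <- sample_pool(TRUE)
  wt_freq <- sample_pool(FALSE)

  mut_depth <- stats::rpois(m, p$mean_depth)
  wt_depth <- stats::rpois(m, p$mean_depth)
  mut_alt <- stats::rbinom(m, mut_depth, mut_freq)
  wt_alt <- stats::rbinom(m, wt_depth, wt_freq)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  impact <- sample(names(p$impact_probs), m, replace = TRUE,
                   prob = p$impact_probs)
  causal_idx <- which(mk$chrom == p$causal_chrom & mk$pos == p$causal_pos)
  impact[causal_idx] <- "HIGH"
  ref[causal_idx] <- "G"; alt[causal_idx] <- "A"

  pe <- p$phenotyping_error
  expected <- data.frame(
    chrom = mk$chrom, pos = mk$pos,
    exp_mut_freq = ifelse(linked, (1 - pe) * (1 - r) + pe * r, 0.5),
    exp_wt_freq = ifelse(linked, (1 - pe) * r + pe * (1 - r), 0.5)
  )

  sites <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt,
                      mut_depth = mut_depth, mut_alt = mut_alt,
                      wt_depth = wt_depth, wt_alt = wt_alt,
                      impact = impact, row.names = NULL)
  list(sites = sites,
       truth = list(causal_chrom = p$causal_chrom, causal_pos = p$causal_pos,
                    expected = expected))
}

#' Write and read pooled variant tables as VCF 4.2
#'
#' The VCF carries two samples, `MUT` and `WT`, with FORMAT fields `DP`
#' (total depth) and `AD` (ref,alt depths), and the predicted functional
#' impact in the INFO field `IMPACT`. `read_pool_vcf()` parses the file
#' with \pkg{vcfR} and returns the same site-table layout the simulator
#' produces (`impact = "NONE"` where the INFO field is absent).
#'
#' @param sites A site table as produced by [generate_pool_counts()].
#' @param path File path.
#' @param contigs Optional data frame (`name`, `length`) for the header.
#' @return `write_pool_vcf()` returns `path` invisibly;
#'   `read_pool_vcf()` returns a site data frame.
#' @export
write_pool_vcf <- function(sites, path, contigs = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "mut_depth", "mut_alt",
            "wt_depth", "wt_alt", "impact")
  stopifnot(all(need %in% names(sites)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mucquant pooled-segregant simulator")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", contigs$name,
                          as.integer(contigs$length)))
  }
  hdr <- c(hdr,
           paste0("##INFO=<ID=IMPACT,Number=1,Type=String,",
                  "Description=\"Predicted functional impact\">"),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "MUT", "WT", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tIMPACT=%s\tDP:AD\t%d:%d,%d\t%d:%d,%d",
                  sites$chrom, as.integer(sites$pos), sites$ref, sites$alt,
                  sites$impact,
                  as.integer(sites$mut_depth),
                  as.integer(sites$mut_depth - sites$mut_alt),
                  as.integer(sites$mut_alt),
                  as.integer(sites$wt_depth),
                  as.integer(sites$wt_depth - sites$wt_alt),
                  as.integer(sites$wt_alt))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_pool_vcf
#' @export
read_pool_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  if (!all(c("MUT", "WT") %in% samples)) {
    stop("VCF must contain samples MUT and WT", call. = FALSE)
  }
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  alt_of <- function(x) as.integer(vapply(strsplit(x, ","), `[`, "", 2L))
  impact <- vcfR::extract.info(v, "IMPACT")
  impact[is.na(impact)] <- "NONE"
  data.frame(chrom = unname(fix[, "CHROM"]),
             pos = as.numeric(fix[, "POS"]),
             ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
             mut_depth = unname(dp[, "MUT"]),
             mut_alt = alt_of(unname(ad[, "MUT"])),
             wt_depth = unname(dp[, "WT"]),
             wt_alt = alt_of(unname(ad[, "WT"])),
             impact = unname(impact), row.names = NULL)
}
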