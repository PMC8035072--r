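#' Genome-size estimation from flow-cytometric G1 peaks
#'
#' Estimates nuclear DNA content against an internal standard:
#' `2C pg = sample G1 peak mean x standard 2C DNA content /
#' standard G1 peak mean`, aggregated over replicate runs, then converted
#' to gigabases with 1 pg DNA = 0.978 Gb; the monoploid (1C) size is half
#' the 2C value.
#'
#' @param replicates `data.frame` with columns `sample_g1_mean` and
#'   `standard_g1_mean`, one row per replicate run (a single pair is fine).
#' @param standard_2c_pg 2C DNA content of the internal standard in pg.
#' @param aggregate `"mean_of_ratios"` (default; replicate runs are
#'   averaged on the ratio scale, matching per-day replicate analysis) or
#'   `"ratio_of_means"`.
#' @return List with `pg_2c`, `gb_2c`, `gb_1c` and `n_replicates`.
#' @examples
#' estimate_genome_size(
#'   data.frame(sample_g1_mean = c(176, 180), standard_g1_mean = c(100, 101)),
#'   standard_2c_pg = 9.09)
#' @export
estimate_genome_size <- function(replicates, standard_2c_pg,
                                 aggregate = c("mean_of_ratios",
                                               "ratio_of_means")) {
  aggregate <- match.arg(aggregate)
  rep <- as.data.frame(replicates)
  stop_if_not_scalar_pos(standard_2c_pg, "standard_2c_pg")
  if (any(rep$sample_g1_mean <= 0) || any(rep$standard_g1_mean <= 0)) {
    stop("peak means must be positive", call. = FALSE)
  }
  ratio <- if (aggregate == "mean_of_ratios") {
    mean(rep$sample_g1_mean / rep$standard_g1_mean)
  } else {
    mean(rep$sample_g1_mean) / mean(rep$standard_g1_mean)
  }
  pg_2c <- ratio * standard_2c_pg
  list(pg_2c = pg_2c,
       gb_2c = pg_2c * 0.978,
       gb_1c = pg_2c * 0.978 / 2,
       n_replicates = nrow(rep))
}
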