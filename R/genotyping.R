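#' Tabulate target-site genotype calls into allele/genotype frequencies
#'
#' Counts ryanodine-receptor position-4790 genotype calls (alleles I =
#' wildtype, M and K = resistance) per group. Allele pairs are unordered
#' (I/M and M/I are the same genotype). A group is flagged positive when
#' at least one non-I allele is observed in any individual.
#'
#' @param calls A data.frame with columns \code{individual_id},
#'   \code{population}, \code{allele_1}, \code{allele_2} and optionally
#'   \code{state}, \code{season}.
#' @param group_by Grouping column, default \code{"population"}.
#' @return A data.frame with one row per group: \code{n_individuals},
#'   genotype counts (\code{n_II}, \code{n_IM}, \code{n_IK}, \code{n_MM},
#'   \code{n_MK}, \code{n_KK}), allele frequencies (\code{freq_I},
#'   \code{freq_M}, \code{freq_K}), \code{wildtype_freq},
#'   \code{resistance_freq} and the logical \code{positive}.
#' @examples
#' calls <- data.frame(individual_id = 1:2, population = "P",
#'                     allele_1 = c("M", "I"), allele_2 = c("M", "K"))
#' tabulate_genotypes(calls)[, c("freq_I", "freq_M", "freq_K")]
#' @export
tabulate_genotypes <- function(calls, group_by = "population") {
  needed <- c("individual_id", group_by, "allele_1", "allele_2")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols) > 0L) {
    stop("genotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  valid <- c("I", "M", "K")
  bad <- which(!(calls$allele_1 %in% valid) | !(calls$allele_2 %in% valid))
  if (length(bad) > 0L) {
    stop("unknown allele symbol (expected I, M or K) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  geno_classes <- c("II", "IM", "IK", "MM", "MK", "KK")
  # unordered pair -> canonical label in I < M < K order
  canon <- function(a1, a2) {
    o <- match(a1, valid) <= match(a2, valid)
    paste0(ifelse(o, a1, a2), ifelse(o, a2, a1))
  }
  geno <- canon(calls$allele_1, calls$allele_2)
  groups <- unique(calls[[group_by]])
  if (length(groups) == 0L) stop("no genotype calls", call. = FALSE)
  rows <- lapply(groups, function(g) {
    in_g <- calls[[group_by]] == g
    gg <- geno[in_g]
    counts <- vapply(geno_classes, function(cl) sum(gg == cl), numeric(1))
    alleles <- c(calls$allele_1[in_g], calls$allele_2[in_g])
    af <- vapply(valid, function(a) mean(alleles == a), numeric(1))
    out <- data.frame(group = g, n_individuals = sum(in_g),
                      stringsAsFactors = FALSE)
    for (cl in geno_classes) out[[paste0("n_", cl)]] <- counts[[cl]]
    out$freq_I <- af[["I"]]; out$freq_M <- af[["M"]]; out$freq_K <- af[["K"]]
    out$wildtype_freq <- af[["I"]]
    out$resistance_freq <- af[["M"]] + af[["K"]]
    out$positive <- out$resistance_freq > 0
    out
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- group_by
  out
}

#' Rank genotypes by pooled abundance
#'
#' Pools genotype counts across frequency tables (typically one per
#' season), sorts by count with lexicographic tie-breaking, and renders a
#' field-style ranking string over the observed (count > 0) genotypes
#' where the separator reflects the magnitude gap between neighbours
#' (">>>" for a >= 10-fold drop, ">>" for >= 3-fold, ">" otherwise).
#'
#' @param tables A frequency table from [tabulate_genotypes()] or a list
#'   of them.
#' @return A list with \code{counts} (named, sorted), \code{order}
#'   (genotype labels, most abundant first) and \code{ranking} (the
#'   formatted string).
#' @export
rank_genotypes <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0L) stop("no frequency tables", call. = FALSE)
  geno_classes <- c("II", "IM", "IK", "MM", "MK", "KK")
  pooled <- vapply(geno_classes, function(cl) {
    sum(vapply(tables, function(t) sum(t[[paste0("n_", cl)]]), numeric(1)))
  }, numeric(1))
  ord <- order(-pooled, geno_classes)
  counts <- pooled[ord]
  labels <- geno_classes[ord]
  pretty <- function(cl) {
    paste0(substr(cl, 1, 1), "/", substr(cl, 2, 2), "4790")
  }
  seen <- counts > 0
  obs_counts <- counts[seen]
  obs_labels <- labels[seen]
  ranking <- ""
  if (length(obs_counts) > 0L) {
    seps <- character(0)
    if (length(obs_counts) > 1L) {
      ratio <- obs_counts[-length(obs_counts)] / obs_counts[-1L]
      seps <- ifelse(ratio >= 10, ">>>", ifelse(ratio >= 3, ">>", ">"))
    }
    ranking <- pretty(obs_labels[1L])
    for (i in seq_along(seps)) {
      ranking <- paste(ranking, seps[i], pretty(obs_labels[i + 1L]))
    }
  }
  list(counts = counts, order = labels, ranking = ranking)
}

#' Genotype-phenotype association across populations
#'
#' Ordinary least-squares regression of discriminating-dose survival
#' (100 - mortality \%) on the resistance-allele frequency (M + K) across
#' populations, joined by population label. Reports the regression F
#' statistic on (1, n - 2) df (numerically the square of the slope t
#' statistic), the absolute correlation R with its sign retained
#' separately, and the F-test p-value.
#'
#' @param freq_table Output of [tabulate_genotypes()].
#' @param mortality_table Output of [summarize_discriminating_dose()].
#' @return A list of class \code{"association"} with \code{slope},
#'   \code{intercept}, \code{f_stat}, \code{df1}, \code{df2}, \code{r}
#'   (absolute), \code{r_signed}, \code{p_value}, \code{n_populations},
#'   \code{unmatched} (labels present on one side only).
#' @export
associate_mortality <- function(freq_table, mortality_table) {
  merged <- merge(freq_table[, c("population", "resistance_freq")],
                  mortality_table[, c("population", "mortality_pct")],
                  by = "population")
  unmatched <- c(setdiff(freq_table$population, merged$population),
                 setdiff(mortality_table$population, merged$population))
  n <- nrow(merged)
  if (n < 3L) {
    stop("fewer than 3 populations with both genotype and mortality data",
         call. = FALSE)
  }
  x <- merged$resistance_freq
  y <- 100 - merged$mortality_pct
  if (stats::var(x) == 0) {
    stop("resistance-allele frequency has zero variance across populations",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r_signed <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  r2 <- r_signed^2
  f_stat <- if (r2 >= 1) Inf else (n - 2L) * r2 / (1 - r2)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    f_stat = f_stat, df1 = 1L, df2 = n - 2L,
    r = abs(r_signed), r_signed = r_signed,
    p_value = stats::pf(f_stat, 1L, n - 2L, lower.tail = FALSE),
    n_populations = n, unmatched = unmatched
  ), class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf(
    "Survival ~ resistance-allele frequency: F = %.1f, df = 1, %d, R = %.3f, p = %.3g\n",
    x$f_stat, x$df2, x$r, x$p_value))
  if (length(x$unmatched) > 0L) {
    cat("  unmatched populations:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}
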