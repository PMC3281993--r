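#' Windowed tumour/normal copy-number comparison
#'
#' Read counts in fixed non-overlapping genomic windows (2 kb by default)
#' are compared between a tumour and a normal genome. Each window's log2
#' ratio is `log2((t/T)/(n/N))`, where `T` and `N` are the genome-wide count
#' totals. Departure from the genome-wide proportion is scored with a
#' two-sided exact binomial test of `t` successes in `t + n` trials with
#' success probability `T/(T + N)`; windows with `p < alpha` are flagged.
#' Windows with zero tumour reads (candidate homozygous deletions) get the
#' plotting sentinel log2 ratio of -4; windows with reads only in the tumour
#' get +4.
#'
#' @param tumor_counts,normal_counts Data frames on the same window grid,
#'   columns `contig`, `start` (0-based, fixed width) and `count`.
#' @param window Window width in bp (metadata only; carried into the output).
#' @param alpha Flagging threshold on the binomial p value.
#' @return A tibble of class `copy_number_windows`: `contig`, `start`,
#'   `end`, `tumor_count`, `normal_count`, `log2_ratio`, `p_value`, `flag`.
#' @export
copy_number_windows <- function(tumor_counts, normal_counts,
                                window = 2000, alpha = 1e-5) {
  tumor_counts <- as_tibble(tumor_counts)
  normal_counts <- as_tibble(normal_counts)
  stopifnot(all(c("contig", "start", "count") %in% names(tumor_counts)),
            all(c("contig", "start", "count") %in% names(normal_counts)))
  tk <- paste(tumor_counts$contig, tumor_counts$start)
  nk <- paste(normal_counts$contig, normal_counts$start)
  if (length(tk) != length(nk) || !all(sort(tk) == sort(nk))) {
    abort("tumour and normal counts are not on the same window grid")
  }
  merged <- inner_join(
    tumor_counts |> rename(tumor_count = "count"),
    normal_counts |> rename(normal_count = "count"),
    by = c("contig", "start")
  )
  t_total <- sum(merged$tumor_count)
  n_total <- sum(merged$normal_count)
  if (t_total <= 0 || n_total <= 0) {
    abort("genome-wide totals must be positive in both genomes")
  }
  p0 <- t_total / (t_total + n_total)
  out <- merged |>
    mutate(
      end = .data$start + window,
      log2_ratio = case_when(
        .data$tumor_count == 0 & .data$normal_count == 0 ~ NA_real_,
        .data$tumor_count == 0 ~ -4,
        .data$normal_count == 0 ~ 4,
        TRUE ~ log2((.data$tumor_count / t_total) /
                      (.data$normal_count / n_total))
      ),
      p_value = purrr::map2_dbl(.data$tumor_count, .data$normal_count,
        function(t, n) {
          if (t + n == 0) return(1)
          binom.test(t, t + n, p = p0, alternative = "two.sided")$p.value
        }),
      flag = .data$p_value < alpha
    ) |>
    select("contig", "start", "end", "tumor_count", "normal_count",
           "log2_ratio", "p_value", "flag")
  structure(out, window = window, alpha = alpha,
            class = c("copy_number_windows", class(out)))
}

#' Plot windowed copy-number ratios
#'
#' Mirrors the usual per-chromosome dot plot: one dot per window at its log2
#' ratio, red when the binomial test falls below the flagging threshold,
#' grey otherwise. Zero-tumour-read windows sit at the -4 sentinel.
#'
#' @param object A [copy_number_windows()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.copy_number_windows <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$start, y = .data$log2_ratio,
                               colour = .data$flag)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "window start (bp)", y = "log2(tumour/normal)")
}
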