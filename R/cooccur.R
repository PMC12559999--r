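#' Truncated percentage with two decimals
#'
#' `floor(100 * numerator / denominator * 100) / 100`: truncation toward
#' zero rather than rounding, the convention used for printed
#' partner-sharing percentages (e.g. 26/107 gives 24.29 where rounding
#' would give 24.30).
#'
#' @param numerator,denominator Non-negative counts (vectorised);
#'   denominators must be positive.
#' @return Percent value(s) truncated to two decimals.
#' @examples
#' truncate_percent(26, 107)  # 24.29
#' @export
truncate_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  # small fudge guards against 100*num/den landing epsilon below an exact
  # hundredth in binary floating point
  floor(10000 * numerator / denominator + 1e-9) / 100
}

#' Partner-sharing statistics for pairs of specimens, by OTU pair
#'
#' For each requested OTU pair, enumerates all specimen pairs (cross pairs
#' for distinct OTUs, unordered within-OTU pairs for a same-OTU row), splits
#' them by co-occurrence (identical site id), counts the pairs whose two
#' specimens carry the same fungal partner label, and reports truncated
#' percentages. Specimens without a partner label are excluded from all
#' counts by default (set `keep_unidentified = TRUE` to retain them in the
#' pair universe while still excluding them from sharing counts).
#'
#' @param specimens A data frame with columns `specimen`, `site`, `otu`,
#'   `partner` (partner may be `NA`).
#' @param otu_pairs Character vector of pairs in the form `"A:B"` (use
#'   `"A:A"` for a same-OTU row), or a list of length-2 character vectors.
#' @param keep_unidentified Keep partner-less specimens in the pair counts
#'   (default FALSE).
#' @return A tibble of class `partner_sharing` with one row per OTU pair:
#'   `otu_pair`, `total_pairs`, `cooccurring_pairs`, `noncooccurring_pairs`,
#'   `cooccurring_sharing`, `noncooccurring_sharing`,
#'   `pct_cooccurring_sharing`, `pct_noncooccurring_sharing` (truncated to
#'   two decimals; `NA` for empty categories) and the full-precision
#'   `pct_*_exact` columns.
#' @export
partner_sharing_table <- function(specimens, otu_pairs,
                                  keep_unidentified = FALSE) {
  specimens <- tibble::as_tibble(specimens)
  req <- c("specimen", "site", "otu", "partner")
  if (!all(req %in% names(specimens))) {
    stop("specimen table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(specimens$specimen)) stop("specimen ids must be unique")
  if (is.character(otu_pairs)) {
    otu_pairs <- strsplit(otu_pairs, ":", fixed = TRUE)
  }
  bad <- otu_pairs[lengths(otu_pairs) != 2L]
  if (length(bad)) stop("otu pairs must have exactly two labels")
  if (!keep_unidentified) {
    specimens <- specimens[!is.na(specimens$partner) &
                             specimens$partner != "", ]
  }
  known <- unique(specimens$otu)
  rows <- lapply(otu_pairs, function(p) {
    a <- p[1L]; b <- p[2L]
    if (!(a %in% known)) stop("unknown OTU label: ", a)
    if (!(b %in% known)) stop("unknown OTU label: ", b)
    sa <- specimens[specimens$otu == a, ]
    sb <- specimens[specimens$otu == b, ]
    if (a == b) {
      if (nrow(sa) < 2L) stop("same-OTU row needs >= 2 specimens: ", a)
      nn <- nrow(sa)
      total <- nn * (nn - 1) / 2
      site_n <- table(sa$site)
      coocc <- sum(site_n * (site_n - 1) / 2)
      share_ok <- !is.na(sa$partner) & sa$partner != ""
      p_n <- table(sa$partner[share_ok])
      share_total <- sum(p_n * (p_n - 1) / 2)
      sp_n <- table(paste(sa$site[share_ok], sa$partner[share_ok], sep = "\r"))
      share_coocc <- sum(sp_n * (sp_n - 1) / 2)
    } else {
      total <- nrow(sa) * nrow(sb)
      sites <- union(sa$site, sb$site)
      na_s <- table(factor(sa$site, levels = sites))
      nb_s <- table(factor(sb$site, levels = sites))
      coocc <- sum(na_s * nb_s)
      pa_ok <- !is.na(sa$partner) & sa$partner != ""
      pb_ok <- !is.na(sb$partner) & sb$partner != ""
      cnt_a <- dplyr::count(sa[pa_ok, ], .data$partner)
      cnt_b <- dplyr::count(sb[pb_ok, ], .data$partner)
      jp <- dplyr::inner_join(cnt_a, cnt_b, by = "partner",
                              suffix = c("_a", "_b"))
      share_total <- sum(jp$n_a * jp$n_b)
      cnt_sa <- dplyr::count(sa[pa_ok, ], .data$site, .data$partner)
      cnt_sb <- dplyr::count(sb[pb_ok, ], .data$site, .data$partner)
      jsp <- dplyr::inner_join(cnt_sa, cnt_sb, by = c("site", "partner"),
                               suffix = c("_a", "_b"))
      share_coocc <- sum(jsp$n_a * jsp$n_b)
    }
    noncoocc <- total - coocc
    share_noncoocc <- share_total - share_coocc
    tibble::tibble(
      otu_pair = paste(a, b, sep = " and "),
      total_pairs = as.numeric(total),
      cooccurring_pairs = as.numeric(coocc),
      noncooccurring_pairs = as.numeric(noncoocc),
      cooccurring_sharing = as.numeric(share_coocc),
      noncooccurring_sharing = as.numeric(share_noncoocc),
      pct_cooccurring_sharing = if (coocc > 0)
        truncate_percent(share_coocc, coocc) else NA_real_,
      pct_noncooccurring_sharing = if (noncoocc > 0)
        truncate_percent(share_noncoocc, noncoocc) else NA_real_,
      pct_cooccurring_sharing_exact = if (coocc > 0)
        100 * share_coocc / coocc else NA_real_,
      pct_noncooccurring_sharing_exact = if (noncoocc > 0)
        100 * share_noncoocc / noncoocc else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("partner_sharing", class(out))
  out
}

#' Partner-sharing percentages from supplied pair counts
#'
#' Recomputes the derived cells of a published partner-sharing summary from
#' its raw pair counts: the non-co-occurring count as total minus
#' co-occurring, and both sharing percentages by truncation to two
#' decimals.
#'
#' @param counts A data frame with columns `otu_pair`, `total_pairs`,
#'   `cooccurring_pairs`, `cooccurring_sharing`, `noncooccurring_sharing`.
#' @return The input with `noncooccurring_pairs`,
#'   `pct_cooccurring_sharing` and `pct_noncooccurring_sharing` filled in.
#' @export
partner_sharing_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  req <- c("otu_pair", "total_pairs", "cooccurring_pairs",
           "cooccurring_sharing", "noncooccurring_sharing")
  if (!all(req %in% names(counts))) {
    stop("need columns: ", paste(req, collapse = ", "))
  }
  dplyr::mutate(
    counts,
    noncooccurring_pairs = .data$total_pairs - .data$cooccurring_pairs,
    pct_cooccurring_sharing =
      truncate_percent(.data$cooccurring_sharing, .data$cooccurring_pairs),
    pct_noncooccurring_sharing =
      truncate_percent(.data$noncooccurring_sharing,
                       .data$noncooccurring_pairs)
  )
}
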