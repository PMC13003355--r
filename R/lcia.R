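#' Life-cycle impact characterization and the Relative Impact Ratio
#'
#' The impact layer multiplies the annualized inventory by a
#' characterization-factor table (impact category x inventory line),
#' normalizes category scores to person-equivalents, selects the dominant
#' categories, and compares scenarios pairwise through the Relative Impact
#' Ratio RIR = (IC_BS - IC_CS) / max(IC_BS, IC_CS) with the +-0.5 heatmap
#' classes. Characterization and normalization factors are user-supplied
#' data (licensed database values cannot be shipped); [generate_fixtures()]
#' writes synthetic stand-in tables keyed to the inventory line names.
#'
#' @name lcia
NULL

#' The 18 midpoint impact categories
#'
#' @return Character vector of category codes (GWP, SOD, IR, OFH, FPMF,
#'   OFT, TA, FE, ME, TET, FET, MET, HCT, HNCT, LU, MRS, FRS, WC).
#' @export
impact_categories <- function() {
  c("GWP", "SOD", "IR", "OFH", "FPMF", "OFT", "TA", "FE", "ME", "TET",
    "FET", "MET", "HCT", "HNCT", "LU", "MRS", "FRS", "WC")
}

#' Load or validate a characterization table
#'
#' @param x Data frame (or CSV path) with columns `category`, `line`,
#'   `factor` and optionally `component` (life-cycle component tag:
#'   Resources, Energy, End of life, Air emissions, Byproducts).
#' @return Validated data.frame of class `characterization_table`.
#' @export
characterization_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("category", "line", "factor")
  if (!all(need %in% names(x))) {
    stop("characterization table needs columns: ",
         paste(need, collapse = ", "))
  }
  if (anyNA(x$factor)) stop("characterization factors must not be NA")
  class(x) <- c("characterization_table", "data.frame")
  x
}

#' Characterize an inventory into per-category impacts
#'
#' impact_c = sum over lines of factor_(c, line) x amount_line. Negative
#' (byproduct) inventory lines yield avoided impacts. Inventory lines with
#' no factor in any category are reported in the `uncharacterized`
#' attribute rather than silently dropped.
#'
#' @param inventory An `inventory_table` (or data.frame with `line`,
#'   `value`).
#' @param table A [characterization_table()].
#' @return Data frame of class `impact_result`: `category`, `impact`, plus
#'   per-component contributions when the table carries a `component`
#'   column.
#' @export
characterize <- function(inventory, table) {
  table <- characterization_table(table)
  cats <- unique(table$category)
  amounts <- stats::setNames(inventory$value, inventory$line)
  merged <- table
  merged$amount <- amounts[merged$line]
  merged$amount[is.na(merged$amount)] <- 0
  merged$term <- merged$factor * merged$amount
  impact <- vapply(cats, function(cc) {
    sum(merged$term[merged$category == cc])
  }, 0)
  res <- data.frame(category = cats, impact = unname(impact))
  if ("component" %in% names(table)) {
    comps <- unique(table$component)
    for (cp in comps) {
      res[[paste0("component.", cp)]] <- vapply(cats, function(cc) {
        sum(merged$term[merged$category == cc & merged$component == cp])
      }, 0)
    }
  }
  attr(res, "uncharacterized") <-
    setdiff(inventory$line, unique(table$line))
  class(res) <- c("impact_result", "data.frame")
  res
}

#' Signed contribution shares by life-cycle component
#'
#' Shares are the signed component terms normalized by the sum of their
#' absolute values, so they sum to at most 1 in magnitude and reveal
#' compensating burdens and credits.
#'
#' @param impacts An `impact_result` carrying component columns.
#' @return Data frame `category` x component share columns.
#' @export
contribution_shares <- function(impacts) {
  cc <- grep("^component\\.", names(impacts), value = TRUE)
  if (!length(cc)) stop("impact result has no component breakdown")
  m <- as.matrix(impacts[cc])
  denom <- rowSums(abs(m))
  denom[denom == 0] <- 1
  out <- data.frame(category = impacts$category, sweep(m, 1, denom, "/"))
  names(out) <- c("category", sub("^component\\.", "", cc))
  out
}

#' Relative Impact Ratio of a scenario pair
#'
#' RIR = (ic_bs - ic_cs) / max(ic_bs, ic_cs): 0 for equal impacts, bounded
#' in [-1, 1] for non-negative inputs. With net-avoided (negative) impacts
#' the same formula is applied and the result may leave [-1, 1]; it is
#' flagged via the `"out_of_range"` attribute rather than clamped.
#'
#' @param ic_bs Impact of the bioscrubber scenario.
#' @param ic_cs Impact of the reference (chemical scrubber) scenario.
#' @return RIR value; 0 when both inputs are 0.
#' @export
rir <- function(ic_bs, ic_cs) {
  if (ic_bs == 0 && ic_cs == 0) return(0)
  v <- (ic_bs - ic_cs) / max(ic_bs, ic_cs)
  if (ic_bs >= 0 && ic_cs >= 0) return(v)
  attr(v, "out_of_range") <- abs(v) > 1
  v
}

#' Heatmap class of an RIR value
#'
#' Thresholds at exactly +-0.5: below -0.5 the reference scenario carries
#' the higher impact ("green"), above +0.5 the bioscrubber does ("red"),
#' boundary values are "yellow" (comparable).
#'
#' @param value RIR value(s).
#' @return Character vector: `"green"`, `"yellow"` or `"red"`.
#' @export
classify_rir <- function(value) {
  ifelse(value < -0.5, "green", ifelse(value > 0.5, "red", "yellow"))
}

#' Normalize impacts to person-equivalents and select the top categories
#'
#' PE_c = impact_c / normalization-factor_c. Categories are ranked by |PE|
#' and the smallest prefix whose cumulative |PE| reaches `coverage` of the
#' total is selected, force-including GWP for its policy relevance.
#'
#' @param impacts An `impact_result`.
#' @param norm_factors Data frame (`category`, `factor`, factors > 0) or
#'   named vector.
#' @param coverage Required cumulative share (default 0.95).
#' @param force Categories always included (default `"GWP"`).
#' @return List with `pe` (data.frame category, pe, share, rank),
#'   `selected` (character vector) and `total_pe` (sum of |PE|).
#' @export
normalize_and_select <- function(impacts, norm_factors, coverage = 0.95,
                                 force = "GWP") {
  if (is.data.frame(norm_factors)) {
    nf <- stats::setNames(norm_factors$factor, norm_factors$category)
  } else {
    nf <- norm_factors
  }
  missing <- setdiff(impacts$category, names(nf))
  if (length(missing)) {
    stop("missing normalization factor for: ",
         paste(missing, collapse = ", "))
  }
  if (any(nf[impacts$category] <= 0)) {
    stop("normalization factors must be positive")
  }
  pe <- impacts$impact / nf[impacts$category]
  tot <- sum(abs(pe))
  ord <- order(abs(pe), decreasing = TRUE)
  share <- if (tot > 0) abs(pe) / tot else rep(0, length(pe))
  csum <- cumsum(share[ord])
  if (tot > 0) {
    k <- which(csum >= coverage)[1]
    sel <- impacts$category[ord[seq_len(k)]]
    sel <- union(sel, intersect(force, impacts$category))
  } else {
    sel <- character(0)
  }
  out <- data.frame(
    category = impacts$category, pe = pe, share = share,
    rank = match(seq_along(pe), ord)
  )
  list(pe = out, selected = sel, total_pe = tot)
}
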