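# Double-peak heterozygous base caller for four-channel trace-peak profiles.
# A site is called heteroplasmic when both of its two tallest peaks stand
# clear of the local noise floor and the minor peak is a substantial fraction
# of the major one.

#' Caller parameters
#'
#' Operationalises the "both peaks significantly higher than the basic noise
#' level at neighbouring sites" rule with two unitless thresholds and a
#' window width.
#'
#' @param noise_multiplier `k`: a peak counts as real when its height exceeds
#'   `k` times the windowed noise floor. Must be > 1.
#' @param minor_ratio `r`: minimum minor/major peak-height ratio for a
#'   heterozygous call; in (0, 1\].
#' @param noise_window `w`: number of neighbouring sites on each side used
#'   for the noise floor; >= 1.
#' @return an object of class `caller_params`.
#' @export
caller_params <- function(noise_multiplier = 3, minor_ratio = 0.2,
                          noise_window = 5L) {
  if (noise_multiplier <= 1) stop("noise_multiplier must be > 1")
  if (minor_ratio <= 0 || minor_ratio > 1)
    stop("minor_ratio must be in (0, 1]")
  if (noise_window < 1) stop("noise_window must be >= 1")
  structure(list(noise_multiplier = noise_multiplier,
                 minor_ratio = minor_ratio,
                 noise_window = as.integer(noise_window)),
            class = "caller_params")
}

.trace_heights <- function(profile) {
  if (!all(.BASES %in% names(profile)))
    stop("trace profile needs A, C, G, T channel columns")
  m <- as.matrix(profile[, .BASES])
  if (nrow(m) < 1) stop("empty trace profile")
  if (any(m < 0)) stop("negative peak height in trace profile")
  m
}

#' Local noise floor of a trace profile
#'
#' Median of the non-maximal channel heights (the three channels below the
#' tallest at each site) over the `w`-site window around `position`, the
#' position itself excluded; windows straddling a sequence end are
#' truncated. For a single-site profile the non-maximal channels of the site
#' itself are used.
#'
#' @param profile a trace profile (data.frame with `A`, `C`, `G`, `T`).
#' @param position 1-based site index.
#' @param params a [caller_params()].
#' @return noise floor height (>= 0).
#' @export
noise_floor <- function(profile, position, params = caller_params()) {
  h <- .trace_heights(profile)
  n <- nrow(h)
  if (position < 1 || position > n) stop("position outside profile")
  w <- params$noise_window
  win <- setdiff(max(1, position - w):min(n, position + w), position)
  if (!length(win)) win <- position
  vals <- apply(h[win, , drop = FALSE], 1, function(x) sort(x)[1:3])
  stats::median(vals)
}

#' Call one site of a trace profile
#'
#' The two tallest channels at the site are compared against
#' `k * noise_floor`: if even the tallest fails, the call is `"N"`; if both
#' clear it and the minor/major height ratio is at least `r`, the site is
#' called heterozygous with the two-base IUPAC code; otherwise the tallest
#' channel's base is called. Ties between equal maximal channels are broken
#' lexicographically, so calls are deterministic, and all thresholds are
#' relative, so calls are invariant to uniform rescaling of the heights.
#'
#' @inheritParams noise_floor
#' @return one-row data.frame: `position`, `call`, `peak_major`,
#'   `peak_minor`, `noise_floor`, `is_het`.
#' @export
call_site <- function(profile, position, params = caller_params()) {
  h <- .trace_heights(profile)[position, ]
  ord <- order(-h, .BASES)
  h1 <- h[[ord[1]]]; h2 <- h[[ord[2]]]
  b1 <- .BASES[ord[1]]; b2 <- .BASES[ord[2]]
  fl <- noise_floor(profile, position, params)
  thr <- params$noise_multiplier * fl
  if (h1 <= thr) {
    call <- "N"; het <- FALSE
  } else if (h2 > thr && h2 / h1 >= params$minor_ratio) {
    call <- iupac_code(b1, b2); het <- TRUE
  } else {
    call <- b1; het <- FALSE
  }
  data.frame(position = position, call = call, peak_major = h1,
             peak_minor = h2, noise_floor = fl, is_het = het,
             stringsAsFactors = FALSE)
}

#' Call every site of a trace profile
#'
#' @inheritParams noise_floor
#' @return a `site_calls` data.frame, one row per position, as in
#'   [call_site()].
#' @seealso [het_sites()], [calls_consensus()], [confirm_heteroplasmy()]
#' @export
call_trace <- function(profile, params = caller_params()) {
  h <- .trace_heights(profile)
  out <- do.call(rbind, lapply(seq_len(nrow(h)), function(i)
    call_site(profile, i, params)))
  structure(out, params = params, class = c("site_calls", "data.frame"))
}

#' Heterozygous site positions of a call set
#' @param calls a `site_calls` data.frame from [call_trace()].
#' @return integer positions called heterozygous.
#' @export
het_sites <- function(calls) calls$position[calls$is_het]

#' IUPAC-coded consensus sequence of a call set
#' @param calls a `site_calls` data.frame from [call_trace()].
#' @return a single string (ambiguity codes at heterozygous sites).
#' @export
calls_consensus <- function(calls) paste(calls$call, collapse = "")

#' @export
print.site_calls <- function(x, ...) {
  cat(sprintf("Site calls: %d positions, %d heterozygous, %d no-call\n",
              nrow(x), sum(x$is_het), sum(x$call == "N")))
  hs <- het_sites(x)
  if (length(hs))
    cat("  het sites:", paste(utils::head(hs, 20), collapse = ", "),
        if (length(hs) > 20) "..." else "", "\n")
  invisible(x)
}

#' Confirm heteroplasmy across replicate reads
#'
#' A heterozygous site counts as confirmed only when an independent replicate
#' read of the same specimen is heterozygous at the same position with the
#' same ambiguity code; sites heterozygous in only one replicate (or with
#' discordant codes) are reported as unconfirmed.
#'
#' @param call_a,call_b `site_calls` of equal length for the two replicates.
#' @return list with integer vectors `confirmed` and `unconfirmed`.
#' @export
confirm_heteroplasmy <- function(call_a, call_b) {
  if (nrow(call_a) != nrow(call_b)) stop("replicate call lengths differ")
  ha <- call_a[call_a$is_het, c("position", "call")]
  hb <- call_b[call_b$is_het, c("position", "call")]
  m <- merge(ha, hb, by = "position", suffixes = c("_a", "_b"))
  confirmed <- m$position[m$call_a == m$call_b]
  unconfirmed <- sort(setdiff(union(ha$position, hb$position), confirmed))
  list(confirmed = sort(confirmed), unconfirmed = unconfirmed)
}

#' Audit singleton polymorphisms in an alignment
#'
#' Flags every site at which some base is carried by exactly one isolate
#' while at least one other base is present — the sites whose chromatograms
#' deserve re-inspection before a rare variant is accepted.
#'
#' @param alignment character vector of equal-length called sequences.
#' @return integer vector of flagged 1-based site positions.
#' @export
singleton_audit <- function(alignment) {
  if (length(alignment) < 1) stop("empty alignment")
  chars <- lapply(alignment, seq_chars)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1) stop("ragged alignment")
  m <- do.call(rbind, chars)
  flagged <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    length(tab) >= 2 && any(tab == 1)
  }, logical(1))
  which(flagged)
}
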