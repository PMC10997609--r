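# Canonical enumeration of the 256 NNCGNN flanking contexts, in lexicographic
# order. Positions 3-4 are the CpG itself; the four flanking bases vary.
hexamer_universe <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(n4 = b, n3 = b, n2 = b, n1 = b, stringsAsFactors = FALSE)
  sort(paste0(g$n1, g$n2, "CG", g$n3, g$n4))
})

#' All 256 NNCGNN hexamer contexts
#'
#' @return Character vector of the 256 six-base contexts with a central CpG,
#'   in lexicographic order.
#' @export
all_hexamers <- function() hexamer_universe

is_valid_hexamer <- function(x) {
  nchar(x) == 6L & !is.na(x) & grepl("^[ACGT]{2}CG[ACGT]{2}$", x)
}

#' Reverse complement of an NNCGNN hexamer
#'
#' The central CpG maps onto itself, so the reverse complement of a valid
#' context is again a valid context; applying the operation twice is the
#' identity.
#'
#' @param hexamer Character vector of NNCGNN hexamers.
#' @return Character vector of reverse-complemented hexamers.
#' @examples
#' revcomp_hexamer("AACGTT")  # palindrome
#' revcomp_hexamer("AACGCC")  # "GGCGTT"
#' @export
revcomp_hexamer <- function(hexamer) {
  bad <- !is_valid_hexamer(hexamer)
  if (any(bad))
    mc_data_error(sprintf("invalid NNCGNN hexamer: '%s'", hexamer[which(bad)[1]]))
  comp <- chartr("ACGT", "TGCA", hexamer)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# revcomp over the whole universe, precomputed once (used by symmetrization
# and by the simulator on every strand-cytosine).
hexamer_revcomp_map <- local({
  rc <- chartr("ACGT", "TGCA", hexamer_universe)
  rc <- vapply(strsplit(rc, "", fixed = TRUE),
               function(ch) paste(rev(ch), collapse = ""), character(1))
  names(rc) <- hexamer_universe
  rc
})

#' Construct a hexamer preference/observation profile
#'
#' A profile maps each of the 256 NNCGNN contexts to one finite value: an
#' in-vitro enzyme preference, or the mean observed methylation of CpGs in
#' that context. Observation profiles additionally carry per-context site
#' counts and may hold \code{NA} for contexts never observed.
#'
#' @param values Named numeric vector covering exactly the 256 contexts
#'   (order free; stored in canonical order). \code{NA} marks a missing
#'   (unobserved) context.
#' @param name Label for the enzyme or sample.
#' @param n_sites Optional named integer vector of contributing site counts.
#' @param symmetrized Logical; whether complementary flanks were averaged.
#' @return An object of class \code{hexamer_profile}.
#' @export
hexamer_profile <- function(values, name = "profile", n_sites = NULL,
                            symmetrized = FALSE) {
  if (is.null(names(values)))
    mc_data_error("profile values must be named by hexamer")
  keys <- names(values)
  bad <- keys[!is_valid_hexamer(keys)]
  if (length(bad))
    mc_format_error(sprintf(
      "hexamer(s) not matching NNCGNN: %s", paste(utils::head(bad, 5), collapse = ", ")))
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    mc_format_error(sprintf("duplicate hexamer(s): %s",
                            paste(utils::head(dup, 5), collapse = ", ")))
  }
  missing <- setdiff(hexamer_universe, keys)
  if (length(missing))
    mc_format_error(sprintf("missing hexamer(s): %s",
                            paste(utils::head(missing, 5), collapse = ", ")))
  v <- as.numeric(values[hexamer_universe])
  names(v) <- hexamer_universe
  if (any(is.infinite(v)))
    mc_data_error("profile values must be finite or NA")
  if (!is.null(n_sites)) {
    ns <- rep(0L, 256L)
    names(ns) <- hexamer_universe
    ns[names(n_sites)] <- as.integer(n_sites)
    n_sites <- ns
  }
  structure(list(name = name, values = v, n_sites = n_sites,
                 symmetrized = isTRUE(symmetrized)),
            class = "hexamer_profile")
}

#' @export
print.hexamer_profile <- function(x, ...) {
  n_obs <- sum(!is.na(x$values))
  cat(sprintf("<hexamer_profile> %s: %d/256 contexts%s\n", x$name, n_obs,
              if (x$symmetrized) " (symmetrized)" else ""))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Symmetrize a hexamer profile over complementary flanks
#'
#' Replaces each context's value by the mean of the context and its reverse
#' complement, reflecting the two-fold symmetry of the CpG site. The 256
#' contexts partition into 120 complementary pairs and 16 palindromes;
#' palindromic values are fixed points and the operation is idempotent.
#'
#' @param profile A complete \code{hexamer_profile} (no missing values).
#' @return A symmetrized \code{hexamer_profile}.
#' @export
symmetrize_profile <- function(profile) {
  stopifnot(inherits(profile, "hexamer_profile"))
  v <- profile$values
  if (anyNA(v))
    mc_data_error("cannot symmetrize a profile with missing entries")
  out <- (v + v[hexamer_revcomp_map[names(v)]]) / 2
  names(out) <- names(v)
  hexamer_profile(out, name = profile$name, n_sites = profile$n_sites,
                  symmetrized = TRUE)
}

#' Rank a profile's contexts from most to least preferred
#'
#' Rank 1 is the highest value; ties get the average of the ranks they cover;
#' missing contexts stay unranked (\code{NA}).
#'
#' @param profile A \code{hexamer_profile}, possibly with missing entries.
#' @return Named numeric vector of ranks over the 256 contexts.
#' @export
rank_profile <- function(profile) {
  stopifnot(inherits(profile, "hexamer_profile"))
  v <- profile$values
  if (sum(!is.na(v)) < 3L)
    mc_data_error("fewer than 3 non-missing contexts; cannot rank")
  r <- rank(-v, ties.method = "average", na.last = "keep")
  names(r) <- names(v)
  r
}
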