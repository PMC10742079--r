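# Carbonyl-oxygen binding sites with X/Y/G triplet roles. In the collagen
# repeat Pro-Pro-Gly the first proline occupies the X position (its carbonyl
# accepts the inter-chain Gly-NH hydrogen bond and binds no water), the
# second proline the Y position (~2 waters), and glycine the G position
# (~1 water).

#' Select backbone carbonyl-oxygen binding sites
#'
#' One site per residue: the backbone carbonyl oxygen (atom name "O") of
#' every non-water residue in the requested chains. Roles are assigned from
#' the residue's position within its chain modulo the repeat length,
#' anchored at the chain's first residue; ordering is chain-major then by
#' residue number.
#'
#' @param traj an \code{hs_trajectory}.
#' @param repeat_roles character vector of roles cycled along each chain
#'   (default \code{c("X","Y","G")} for a P-P-G repeat).
#' @param chains chain ids to include; default all non-water chains.
#' @return data.frame of class \code{hs_sites} with columns \code{atom}
#'   (1-based topology row), \code{index} (0-based atom index),
#'   \code{chain_id}, \code{residue_seq}, \code{role}.
#' @export
select_carbonyl_sites <- function(traj, repeat_roles = c("X", "Y", "G"),
                                  chains = NULL) {
  top <- traj$topology
  pep <- top[!top$is_water, , drop = FALSE]
  # default: every non-water chain that actually carries carbonyl oxygens
  # (pseudo-atom chains such as bead scaffolds have none and are skipped)
  if (is.null(chains)) chains <- unique(pep$chain_id[pep$name == "O"])
  missing_ch <- setdiff(chains, unique(pep$chain_id))
  if (length(missing_ch))
    warning("no residues found for chain(s): ", paste(missing_ch, collapse = ", "))
  out <- list()
  p <- length(repeat_roles)
  for (ch in intersect(chains, unique(pep$chain_id))) {
    res <- sort(unique(pep$residue_seq[pep$chain_id == ch]))
    if (length(res) %% p != 0)
      warning(sprintf("chain %s has %d residues, not a multiple of %d; trailing partial repeat still assigned roles",
                      ch, length(res), p))
    role <- repeat_roles[((seq_along(res) - 1L) %% p) + 1L]
    rows <- vapply(res, function(r) {
      hit <- which(pep$chain_id == ch & pep$residue_seq == r & pep$name == "O")
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    keep <- !is.na(rows)
    if (!all(keep))
      warning(sprintf("chain %s: %d residue(s) lack a carbonyl oxygen atom 'O'",
                      ch, sum(!keep)))
    out[[ch]] <- data.frame(
      atom = match(pep$index[rows[keep]], top$index),
      index = pep$index[rows[keep]],
      chain_id = rep(ch, sum(keep)), residue_seq = res[keep],
      role = role[keep], stringsAsFactors = FALSE)
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(atom = integer(), index = integer(), chain_id = character(),
               residue_seq = integer(), role = character(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  class(sites) <- c("hs_sites", "data.frame")
  sites
}
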