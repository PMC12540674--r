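.aa1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Define a mutation site
#'
#' @param resno residue number.
#' @param wt wild-type amino acid (1-letter, canonical).
#' @param chain chain identifier (default "A").
#' @return An object of class `MutationSite` (a one-row data frame).
#' @export
mutation_site <- function(resno, wt, chain = "A") {
  wt <- toupper(as.character(wt))
  if (!wt %in% .aa1)
    stop("wild-type '", wt, "' is not a canonical amino acid", call. = FALSE)
  out <- data.frame(resno = as.integer(resno), wt = wt,
                    chain = as.character(chain), stringsAsFactors = FALSE)
  class(out) <- c("MutationSite", class(out))
  out
}

#' Exhaustively enumerate single-site mutants
#'
#' For each site, the 19 substitutions to the other canonical amino acids
#' plus one wild-type reference entry — 20 entries per site, so 10 sites
#' give 200 entries. The reference row is flagged, carries
#' `ddG_fold = 0` and serves as the per-site baseline of the screen.
#'
#' @param sites list of `MutationSite` objects (or a data frame with
#'   columns `resno`, `wt`, `chain`); no duplicate (chain, resno).
#' @return data frame of mutants: `site` (label like "K1"), `chain`,
#'   `resno`, `wt`, `target`, `is_wt_ref`, `mutant` (label like "K1L").
#' @export
enumerate_mutants <- function(sites) {
  if (inherits(sites, "MutationSite")) sites <- list(sites)
  if (is.data.frame(sites)) {
    sites <- lapply(seq_len(nrow(sites)), function(i)
      mutation_site(sites$resno[i], sites$wt[i],
                    if ("chain" %in% names(sites)) sites$chain[i] else "A"))
  }
  if (!length(sites)) stop("no mutation sites given", call. = FALSE)
  df <- do.call(rbind, sites)
  key <- paste(df$chain, df$resno)
  if (anyDuplicated(key))
    stop("duplicate site(s): ", paste(unique(key[duplicated(key)]),
                                      collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    wt <- df$wt[i]
    targets <- c(wt, setdiff(.aa1, wt))       # wt reference first
    data.frame(site = paste0(wt, df$resno[i]), chain = df$chain[i],
               resno = df$resno[i], wt = wt, target = targets,
               is_wt_ref = targets == wt,
               mutant = paste0(wt, df$resno[i], targets),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Binding free-energy change of a mutant relative to wild type
#'
#' @param mut_dG mutant binding free energy, kcal/mol.
#' @param wt_dG wild-type binding free energy, kcal/mol.
#' @return `mut_dG - wt_dG` (kcal/mol); positive values mean weakened
#'   binding.
#' @export
ddg_bind <- function(mut_dG, wt_dG) {
  if (any(!is.finite(mut_dG)) || any(!is.finite(wt_dG)))
    stop("binding free energies must be finite", call. = FALSE)
  mut_dG - wt_dG
}

#' Dual free-energy-criterion screen for low-activity mutants
#'
#' Stage 1 (stability) keeps substitutions whose folding penalty is small,
#' `|ddG_fold| <= fold_cut`; stage 2 (affinity) keeps, among those, the
#' ones whose binding is weakened enough, `ddG_bind >= bind_cut` with
#' `ddG_bind = dG_bind - wt_dG`. Both comparisons are inclusive. Per site
#' with at least one affinity survivor, the finalist is the mutant with the
#' highest (weakest) `dG_bind`; exact ties go to the alphabetically first
#' target residue. Wild-type reference rows pass no stage and are counted
#' separately.
#'
#' @param mutants data frame from [enumerate_mutants()] with provider
#'   columns `ddG_fold` (all non-reference rows) and `dG_bind` (at least
#'   all stability survivors).
#' @param fold_cut stability cutoff, kcal/mol (default 2).
#' @param bind_cut affinity cutoff, kcal/mol (default 2).
#' @param wt_dG wild-type binding free energy, kcal/mol (default -10.17).
#' @return An object of class `ScreenResult`: list with `mutants` (the
#'   table plus `ddG_bind`, `stability_pass`, `affinity_pass`, `finalist`),
#'   `finalists` (character vector of mutant labels), `counts` (named:
#'   `enumerated`, `substitutions`, `stability_pass`, `affinity_pass`,
#'   `finalists`) and `per_site_stability` (named integer vector).
#' @export
dual_criterion_screen <- function(mutants, fold_cut = 2, bind_cut = 2,
                                  wt_dG = -10.17) {
  m <- as.data.frame(mutants)
  if (!"ddG_fold" %in% names(m))
    stop("provider column 'ddG_fold' missing", call. = FALSE)
  sub <- !m$is_wt_ref
  bad <- sub & !is.finite(m$ddG_fold)
  if (any(bad))
    stop("ddG_fold missing for mutant(s): ",
         paste(utils::head(m$mutant[bad], 5L), collapse = ", "),
         call. = FALSE)
  m$stability_pass <- sub & abs(m$ddG_fold) <= fold_cut
  if (!"dG_bind" %in% names(m)) m$dG_bind <- NA_real_
  need_bind <- m$stability_pass & !is.finite(m$dG_bind)
  if (any(need_bind))
    stop("dG_bind missing for stability survivor(s): ",
         paste(utils::head(m$mutant[need_bind], 5L), collapse = ", "),
         call. = FALSE)
  m$ddG_bind <- ifelse(is.finite(m$dG_bind), m$dG_bind - wt_dG, NA_real_)
  m$affinity_pass <- m$stability_pass & !is.na(m$ddG_bind) &
    m$ddG_bind >= bind_cut
  m$finalist <- FALSE
  for (s in unique(m$site)) {
    rows <- which(m$site == s & m$affinity_pass)
    if (!length(rows)) next
    # weakest binder wins; alphabetical target breaks exact ties
    ord <- rows[order(-m$dG_bind[rows], m$target[rows])]
    m$finalist[ord[1L]] <- TRUE
  }
  out <- list(
    mutants = m,
    finalists = m$mutant[m$finalist],
    counts = c(enumerated = nrow(m),
               substitutions = sum(sub),
               stability_pass = sum(m$stability_pass),
               affinity_pass = sum(m$affinity_pass),
               finalists = sum(m$finalist)),
    per_site_stability = {
      ps <- tapply(m$stability_pass, m$site, sum)
      stats::setNames(as.integer(ps), names(ps))
    })
  class(out) <- "ScreenResult"
  out
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("ScreenResult:", x$counts[["enumerated"]], "enumerated (",
      x$counts[["substitutions"]], "substitutions ),",
      x$counts[["stability_pass"]], "stability pass,",
      x$counts[["affinity_pass"]], "affinity pass;",
      "finalists:", paste(x$finalists, collapse = ", "), "\n")
  invisible(x)
}

#' Apply finalist substitutions to the wild-type sequence
#'
#' @param wt_seq wild-type protein sequence (single string or character
#'   vector of residues).
#' @param finalists data frame with columns `resno`, `wt`, `target` (e.g.
#'   the finalist rows of a `ScreenResult`), or mutant labels like
#'   `"K1L"`.
#' @return named character vector of mutant sequences, one per finalist;
#'   names encode site and target (e.g. `"K1L"`).
#' @export
mutant_sequences <- function(wt_seq, finalists) {
  seq_v <- if (length(wt_seq) == 1L) strsplit(wt_seq, "")[[1L]] else
    as.character(wt_seq)
  if (is.character(finalists)) {
    parsed <- regmatches(finalists,
                         regexec("^([A-Z])([0-9]+)([A-Z])$", finalists))
    if (any(vapply(parsed, length, 1L) != 4L))
      stop("unparseable mutant label(s)", call. = FALSE)
    finalists <- data.frame(
      wt = vapply(parsed, `[`, "", 2L),
      resno = as.integer(vapply(parsed, `[`, "", 3L)),
      target = vapply(parsed, `[`, "", 4L), stringsAsFactors = FALSE)
  }
  finalists <- as.data.frame(finalists)
  if (!nrow(finalists)) return(stats::setNames(character(0), character(0)))
  out <- character(nrow(finalists))
  labs <- character(nrow(finalists))
  for (i in seq_len(nrow(finalists))) {
    pos <- finalists$resno[i]
    if (pos < 1L || pos > length(seq_v))
      stop("residue ", pos, " outside sequence (length ", length(seq_v), ")",
           call. = FALSE)
    if (seq_v[pos] != finalists$wt[i])
      stop("wild-type mismatch at position ", pos, ": sequence has '",
           seq_v[pos], "', site says '", finalists$wt[i], "'", call. = FALSE)
    mut <- seq_v
    mut[pos] <- finalists$target[i]
    out[i] <- paste(mut, collapse = "")
    labs[i] <- paste0(finalists$wt[i], pos, finalists$target[i])
  }
  stats::setNames(out, labs)
}
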