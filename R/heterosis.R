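#' Mid-parent heterosis (percent)
#'
#' `100 * (F1 - MP) / MP` with `MP = (p1 + p2) / 2`.  Undefined (NA, with a
#' warning) when the mid-parent value is zero.
#'
#' @param f1 F1 trait mean.
#' @param p1,p2 parental trait means.
#' @return Percent mid-parent heterosis (vectorized).
#' @export
mid_parent_heterosis <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  out <- 100 * (f1 - mp) / mp
  if (any(mp == 0)) {
    warning("mid-parent value of 0: heterosis undefined")
    out[mp == 0] <- NA_real_
  }
  out
}

#' High-parent (better-parent) heterosis (percent)
#'
#' `100 * (F1 - HP) / HP` with `HP = max(p1, p2)`.
#'
#' @inheritParams mid_parent_heterosis
#' @return Percent high-parent heterosis (vectorized).
#' @export
high_parent_heterosis <- function(f1, p1, p2) {
  hp <- pmax(p1, p2)
  out <- 100 * (f1 - hp) / hp
  if (any(hp == 0)) {
    warning("high-parent value of 0: heterosis undefined")
    out[hp == 0] <- NA_real_
  }
  out
}

#' Heterosis index relative to a check combination
#'
#' `(F1 - check) / check`, a unitless ratio: 0 means equal to the check,
#' 0.5 means 50 percent above it.
#'
#' @param f1 F1 trait mean (vectorized).
#' @param check trait mean of the check (control) combination; must be > 0.
#' @return Heterosis index.
#' @export
heterosis_index <- function(f1, check) {
  if (any(check <= 0)) stop("check value must be > 0")
  (f1 - check) / check
}

#' Per-cross, per-trait heterosis table
#'
#' Computes F1 means from plot-level data, parental means from a parent
#' per-se table, and derives MPH, HPH and (when a check is supplied) the
#' heterosis index for every cross x trait.
#'
#' @param pheno plot-level F1 data.frame with `female`, `male` columns and
#'   trait columns.
#' @param parents parent per-se data.frame: column `parent` plus the same
#'   trait columns (plot-level or already averaged).
#' @param traits trait column names (default: numeric columns shared by both
#'   tables).
#' @param check_value named numeric vector (by trait) or single number: the
#'   check mean used for the heterosis index; or `NULL` to skip HI.
#' @param check_cross length-2 character `c(female, male)`: use that cross's
#'   F1 mean as the check (per trait); overrides `check_value`.
#' @return A data.frame of class `"heterosis_table"` with columns `female`,
#'   `male`, `cross`, `trait`, `f1`, `mp`, `hp`, `mph`, `hph`, `hi`.
#' @export
heterosis_table <- function(pheno, parents, traits = NULL,
                            check_value = NULL, check_cross = NULL) {
  if (is.null(traits)) {
    num_p <- names(pheno)[vapply(pheno, is.numeric, TRUE)]
    num_q <- names(parents)[vapply(parents, is.numeric, TRUE)]
    traits <- setdiff(intersect(num_p, num_q), c("rep", "replicate"))
  }
  if (!length(traits)) stop("no shared trait columns")
  pm <- stats::aggregate(parents[traits], list(parent = parents$parent), mean)
  crosses <- unique(pheno[c("female", "male")])
  f1m <- stats::aggregate(pheno[traits], pheno[c("female", "male")], mean)
  miss <- setdiff(c(unique(crosses$female), unique(crosses$male)),
                  pm$parent)
  if (length(miss))
    stop("parents without per-se values: ", paste(miss, collapse = ", "))
  rows <- list()
  for (tr in traits) {
    f1 <- f1m[[tr]]
    p1 <- pm[[tr]][match(f1m$female, pm$parent)]
    p2 <- pm[[tr]][match(f1m$male, pm$parent)]
    mp <- (p1 + p2) / 2; hp <- pmax(p1, p2)
    chk <- NA_real_
    if (!is.null(check_cross)) {
      hit <- f1m$female == check_cross[1] & f1m$male == check_cross[2]
      if (!any(hit)) stop("check cross not found")
      chk <- f1[hit][1]
    } else if (!is.null(check_value)) {
      chk <- if (!is.null(names(check_value)))
        check_value[[tr]] else check_value
    }
    rows[[tr]] <- data.frame(
      female = f1m$female, male = f1m$male,
      cross = paste(f1m$female, f1m$male, sep = " x "),
      trait = tr, f1 = f1, mp = mp, hp = hp,
      mph = suppressWarnings(mid_parent_heterosis(f1, p1, p2)),
      hph = suppressWarnings(high_parent_heterosis(f1, p1, p2)),
      hi = if (is.na(chk)) NA_real_ else heterosis_index(f1, chk),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("heterosis_table", "data.frame")
  out
}

#' Rank crosses by heterosis index
#'
#' Orders crosses for one trait by descending heterosis index (falling back
#' to MPH when no check was supplied), ties broken by F1 mean then by cross
#' name, and returns the strongest and weakest combinations.  When a group
#' assignment is given, each cross is annotated with whether its parents
#' come from different heterotic groups.
#'
#' @param h a `"heterosis_table"`.
#' @param trait trait to rank on.
#' @param top_n,bottom_n numbers of strong/weak combinations to return.
#' @param groups optional `"group_assignment"` or named vector for the
#'   between-group annotation.
#' @return A data.frame with the selected rows, a `rank` column and logical
#'   `between_groups` (NA without `groups`).
#' @export
rank_crosses <- function(h, trait, top_n = 10, bottom_n = 10,
                         groups = NULL) {
  d <- h[h$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("trait not present: ", trait)
  if (top_n + bottom_n > nrow(d))
    stop("top_n + bottom_n exceeds number of crosses")
  score <- if (all(is.na(d$hi))) d$mph else d$hi
  ord <- order(-score, -d$f1, d$cross)
  d <- d[ord, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  if (!is.null(groups)) {
    gv <- if (inherits(groups, "group_assignment")) groups$groups else groups
    d$between_groups <- gv[d$female] != gv[d$male]
  } else d$between_groups <- NA
  sel <- c(seq_len(top_n), if (bottom_n > 0)
    seq(nrow(d) - bottom_n + 1, nrow(d)))
  out <- d[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
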