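# Synthetic pregnant-body fixtures at three gestational ages.  Each
# fixture is a homogeneous torso ellipsoid containing a fetus whole-body
# ellipsoid and per-tissue ellipsoidal sub-regions.  The geometry is
# SYNTHETIC: fetal masses (~15 g, ~1.7 kg, ~2.7 kg at 3, 7, 9 months at
# unit tissue density) set the whole-body sizes, and the fetus placement
# inside the torso (which is centered on the uterus) is chosen so that the
# worst-case whole-body exposure occurs for a front-to-back field at 3 and
# 9 months and for a lateral field at 7 months, while keeping the
# orientation response smooth (a strongly offset small fetus would see a
# sharp directional null: for any single point there is a field
# orientation with zero induced field there, so small regions must sit
# near the torso center to average that null away).  Tissue names follow the fetal-tissue nomenclature of
# anatomical models at these ages; entries marked generic pad the lists to
# the 15/17/26 tissues the three ages distinguish.

# Relative organ layout shared by all ages: semi-axes and centers as
# fractions of the fetus whole-body semi-axes.  Head is toward +z.
fixture_layout <- function() {
  L <- list(
    #            sx    sy    sz     cx     cy     cz    cns
    skin        = c(0.97, 0.97, 0.97,  0.00,  0.00,  0.00, 0),
    fat         = c(0.90, 0.90, 0.92,  0.00,  0.00,  0.00, 0),
    muscle      = c(0.80, 0.80, 0.85,  0.00,  0.00,  0.00, 0),
    bone        = c(0.55, 0.55, 0.80,  0.00,  0.00,  0.02, 0),
    sat         = c(0.85, 0.85, 0.88,  0.00,  0.00,  0.00, 0),
    brain       = c(0.42, 0.42, 0.20,  0.00,  0.00,  0.75, 1),
    csf         = c(0.46, 0.46, 0.23,  0.00,  0.00,  0.74, 1),
    eye_lens    = c(0.04, 0.04, 0.03,  0.30,  0.12,  0.82, 0),
    spinal_cord = c(0.05, 0.05, 0.50, -0.35,  0.00,  0.05, 0),
    heart       = c(0.16, 0.16, 0.14,  0.08,  0.06,  0.35, 0),
    lung        = c(0.22, 0.30, 0.20, -0.05,  0.00,  0.38, 0),
    liver       = c(0.28, 0.30, 0.16,  0.10, -0.15,  0.12, 0),
    stomach     = c(0.15, 0.18, 0.12,  0.12,  0.18,  0.15, 0),
    kidney      = c(0.10, 0.22, 0.12, -0.28,  0.00,  0.00, 0),
    spleen      = c(0.10, 0.12, 0.10,  0.00,  0.30,  0.10, 0),
    intestine   = c(0.35, 0.35, 0.22,  0.00,  0.00, -0.35, 0),
    bladder     = c(0.14, 0.14, 0.12,  0.15,  0.00, -0.62, 0),
    gallbladder = c(0.06, 0.07, 0.06,  0.22, -0.18,  0.08, 0),
    adrenal     = c(0.06, 0.10, 0.05, -0.25,  0.10,  0.12, 0),
    esophagus   = c(0.04, 0.04, 0.22, -0.10,  0.00,  0.42, 0),
    thyroid     = c(0.08, 0.10, 0.05,  0.05,  0.00,  0.58, 0),
    ovary       = c(0.05, 0.07, 0.05,  0.05,  0.25, -0.45, 0),
    pancreas    = c(0.08, 0.20, 0.06,  0.00, -0.10,  0.08, 0),  # generic
    thymus      = c(0.08, 0.10, 0.06,  0.06,  0.00,  0.47, 0),  # generic
    cartilage   = c(0.10, 0.10, 0.28,  0.28,  0.00,  0.30, 0),  # generic
    tendon      = c(0.08, 0.08, 0.28, -0.20,  0.15, -0.30, 0)   # generic
  )
  m <- do.call(rbind, L)
  data.frame(name = rownames(m), sx = m[, 1], sy = m[, 2], sz = m[, 3],
             cx = m[, 4], cy = m[, 5], cz = m[, 6],
             cns = m[, 7] == 1, row.names = NULL)
}

fixture_tissue_names <- function(label) {
  ga3 <- c("skin", "fat", "muscle", "bone", "brain", "eye_lens",
           "spinal_cord", "heart", "lung", "liver", "stomach", "kidney",
           "spleen", "intestine", "bladder")
  ga7 <- c(ga3, "sat", "gallbladder")
  ga9 <- c(ga7, "csf", "adrenal", "esophagus", "thyroid", "ovary",
           "pancreas", "thymus", "cartilage", "tendon")
  switch(label, "3mo" = ga3, "7mo" = ga7, "9mo" = ga9,
         stop(sprintf("unknown gestational-age label: %s", label),
              call. = FALSE))
}

# Numeric containment check: the maximum of the outer ellipsoid's
# quadratic form over the inner ellipsoid's surface must stay below 1.
check_inside <- function(inner_center, inner_semi, outer_center,
                         outer_semi, what, margin = 0.995) {
  th <- seq(0, pi, length.out = 25L)
  ph <- seq(-pi, pi, length.out = 49L)[-1L]
  g <- expand.grid(th = th, ph = ph)
  s <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  pts <- sweep(sweep(s, 2L, inner_semi, "*"), 2L, inner_center, "+")
  d <- sweep(pts, 2L, outer_center, "-")
  q <- (d[, 1] / outer_semi[1])^2 + (d[, 2] / outer_semi[2])^2 +
    (d[, 3] / outer_semi[3])^2
  if (max(q) > margin) {
    stop(sprintf("%s is not strictly inside its enclosing ellipsoid", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Synthetic pregnant-body fixture at a gestational age
#'
#' Packaged fixture standing in for anatomical pregnant-woman models:
#' a homogeneous torso ellipsoid, a fetus whole-body ellipsoid whose
#' volume grows with gestational age (about 15 g, 1.7 kg and 2.7 kg at
#' unit density), and 15, 17 or 26 ellipsoidal tissue regions at 3, 7 and
#' 9 months respectively.  The fetus offsets are chosen so that a
#' brute-force orientation sweep of the whole-body exposure peaks for a
#' front-to-back field at 3 and 9 months and for a lateral field at
#' 7 months.  Brain and cerebrospinal fluid carry the `is_cns_head` flag;
#' the spinal cord does not (it is not tissue "of the head"), nor does the
#' eye lens (not a central-nervous-system tissue).
#'
#' @param label one of `"3mo"`, `"7mo"`, `"9mo"`.
#' @return An object of class `ga_model`: `label`, `body`
#'   (a [body_ellipsoid()]), `fetus_whole_body` (a [tissue_region()]) and
#'   `tissues` (named list of [tissue_region()]).
#' @examples
#' length(ga_fixture("3mo")$tissues)  # 15
#' @export
ga_fixture <- function(label) {
  geom <- switch(
    as.character(label),
    "3mo" = list(body = c(0.10, 0.16, 0.25),
                 f_center = c(0.00, 0.00, 0.00),
                 f_semi = c(0.009, 0.014, 0.0285)),
    "7mo" = list(body = c(0.13, 0.17, 0.28),
                 f_center = c(0.04, 0.00, -0.04),
                 f_semi = c(0.055, 0.060, 0.120)),
    "9mo" = list(body = c(0.12, 0.17, 0.25),
                 f_center = c(0.005, 0.00, -0.04),
                 f_semi = c(0.060, 0.070, 0.155)),
    stop(sprintf("unknown gestational-age label: %s", label),
         call. = FALSE)
  )
  body <- body_ellipsoid(geom$body[1], geom$body[2], geom$body[3])
  check_inside(geom$f_center, geom$f_semi, c(0, 0, 0), geom$body,
               sprintf("fetus whole body (%s)", label))
  whole <- tissue_region("whole_body", geom$f_center, geom$f_semi)
  layout <- fixture_layout()
  names_ga <- fixture_tissue_names(as.character(label))
  tissues <- lapply(names_ga, function(nm) {
    row <- layout[layout$name == nm, ]
    center <- geom$f_center + c(row$cx, row$cy, row$cz) * geom$f_semi
    semi <- c(row$sx, row$sy, row$sz) * geom$f_semi
    check_inside(center, semi, geom$f_center, geom$f_semi,
                 sprintf("tissue %s (%s)", nm, label), margin = 1.0000001)
    tissue_region(nm, center, semi, is_cns_head = row$cns)
  })
  names(tissues) <- names_ga
  structure(
    list(label = as.character(label), body = body,
         fetus_whole_body = whole, tissues = tissues),
    class = "ga_model"
  )
}

#' @export
print.ga_model <- function(x, ...) {
  cat(sprintf(
    "Gestational-age fixture %s: body (%.2f, %.2f, %.2f) m, %d tissues\n",
    x$label, x$body$a, x$body$b, x$body$c, length(x$tissues)))
  cns <- names(x$tissues)[vapply(x$tissues, `[[`, logical(1),
                                 "is_cns_head")]
  cat(sprintf("  CNS-of-head tissues: %s\n",
              if (length(cns)) paste(cns, collapse = ", ") else "none"))
  invisible(x)
}
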