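#' Configuration for a synthetic irradiation-hybrid population
#'
#' Bundles every parameter of the synthetic population generator. Defaults
#' are calibrated to the greenhouse study conditions the package is designed
#' around: 201 genotypes of which 173 carry indels, 3 clonal replicates,
#' a 19-chromosome poplar genome, indel counts and lengths producing on the
#' order of 450-500 genomic bins with a mean of ~6 overlapping indels each,
#' tree height log-normal with mean 64 and SD 32 cm, a deleterious mean
#' height effect of carrying lesions, and allometric exponents solved so
#' that the model-implied height correlations match the observed +0.76
#' (mean vessel diameter), -0.78 (vessel frequency) and +0.52 (bark
#' thickness).
#'
#' Each trait entry supplies `mean` and either (`sd`, `h2`) or explicit
#' variance components (`V_g`, `V_e`), plus either a target height
#' correlation `cor_th` (the allometric exponent `b` is solved from it) or
#' `b` directly. `h2` is the heritability of the height-independent trait
#' component; for height-dependent traits the realized clonal repeatability
#' also absorbs allometric variance.
#'
#' @param n_lines Number of genotypes.
#' @param frac_lesion_lines Proportion of genotypes carrying indels.
#' @param n_replicates Clonal replicates (ramets) per genotype.
#' @param ploidy Background ploidy of every line.
#' @param indels List: `mean_count` (mean indels per lesion line, >= 1),
#'   `len_meanlog`, `len_sdlog` (log-normal length, bp), `min_len` (bp),
#'   `ins_frac` (insertion proportion).
#' @param height List: population `mean` and `sd` (cm), `h2`
#'   (line-level share of log-height variance), `lesion_penalty`
#'   (multiplicative expected-height ratio lesion/non-lesion), `min` (cm,
#'   truncation floor).
#' @param traits Named list of per-trait parameter lists (see Details).
#' @param planted_effects Data frame with columns `chrom`, `pos`, `trait`,
#'   `effect` (trait units per unit RDS) and optional `side` (`"both"`,
#'   `"del_only"`, `"ins_only"`); `NULL` for none.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_lines = 201,
                       frac_lesion_lines = 173 / 201,
                       n_replicates = 3,
                       ploidy = 2,
                       indels = list(),
                       height = list(),
                       traits = list(),
                       planted_effects = NULL,
                       seed = 1L) {
  ind_def <- list(mean_count = 1.4, len_meanlog = log(8e6),
                  len_sdlog = 0.9, min_len = 1e5, ins_frac = 0.5)
  ind <- utils::modifyList(ind_def, indels)
  h_def <- list(mean = 64, sd = 32, h2 = 0.45, lesion_penalty = 0.75, min = 1)
  h <- utils::modifyList(h_def, height)
  tr_def <- list(
    MVD = list(mean = 26, sd = 4, h2 = 0.49, cor_th = 0.76),
    VF = list(mean = 365, sd = 166, h2 = 0.45, cor_th = -0.78),
    VGI = list(mean = 1.47, sd = 0.1, h2 = 0.47, cor_th = 0),
    MVC = list(mean = 0.78, sd = 0.03, h2 = 0.51, cor_th = 0),
    NF = list(mean = 0.80, sd = 0.04, h2 = 0.50, cor_th = 0),
    BT = list(mean = 608, sd = 349, h2 = 0.37, cor_th = 0.52)
  )
  tr <- tr_def
  for (nm in names(traits)) {
    tr[[nm]] <- if (nm %in% names(tr_def) && is.list(traits[[nm]]))
      utils::modifyList(tr_def[[nm]], traits[[nm]]) else traits[[nm]]
  }
  stopifnot(n_lines >= 1, frac_lesion_lines >= 0, frac_lesion_lines <= 1,
            n_replicates >= 1, ploidy >= 1,
            ind$mean_count >= 1, ind$ins_frac >= 0, ind$ins_frac <= 1,
            h$mean > 0, h$sd >= 0, h$h2 >= 0, h$h2 <= 1,
            h$lesion_penalty > 0)
  if (!is.null(planted_effects)) {
    stopifnot(all(c("chrom", "pos", "trait", "effect") %in%
                    names(planted_effects)))
    if (is.null(planted_effects$side)) planted_effects$side <- "both"
    stopifnot(all(planted_effects$side %in% c("both", "del_only", "ins_only")))
  }
  structure(list(n_lines = n_lines, frac_lesion_lines = frac_lesion_lines,
                 n_replicates = n_replicates, ploidy = ploidy,
                 indels = ind, height = h, traits = tr,
                 planted_effects = planted_effects, seed = as.integer(seed)),
            class = "sim_config")
}

# log-scale parameters of the (untruncated) height model implied by config
height_params <- function(config) {
  h <- config$height
  s2 <- log(1 + (h$sd / h$mean)^2)
  f_l <- config$frac_lesion_lines
  delta <- log(h$lesion_penalty)
  # baseline chosen so the lesion/non-lesion mixture has the target mean
  mu0 <- log(h$mean / ((1 - f_l) + f_l * h$lesion_penalty)) - s2 / 2
  list(mu0 = mu0, delta = delta, s2 = s2,
       s2_g = h$h2 * s2, s2_e = (1 - h$h2) * s2, f_l = f_l)
}

# E[h^k] for the lesion/non-lesion log-normal mixture
height_moment <- function(config, k) {
  p <- height_params(config)
  (1 - p$f_l) * exp(k * p$mu0 + k^2 * p$s2 / 2) +
    p$f_l * exp(k * (p$mu0 + p$delta) + k^2 * p$s2 / 2)
}

# resolve a trait's generative parameters: scale c, exponent b, V_g, V_e
resolve_trait <- function(config, name) {
  tr <- config$traits[[name]]
  if (is.null(tr)) stop("no parameters configured for trait ", name)
  b <- tr$b
  if (is.null(b)) {
    ct <- if (is.null(tr$cor_th)) 0 else tr$cor_th
    var_h <- height_moment(config, 2) - height_moment(config, 1)^2
    b <- if (ct == 0 || var_h <= 0) 0
    else solve_allometric_exponent(config, name)
  }
  c_scale <- tr$mean / height_moment(config, b)
  var_allom <- c_scale^2 * (height_moment(config, 2 * b) -
                              height_moment(config, b)^2)
  if (!is.null(tr$V_g) || !is.null(tr$V_e)) {
    Vg <- if (is.null(tr$V_g)) 0 else tr$V_g
    Ve <- if (is.null(tr$V_e)) 0 else tr$V_e
  } else {
    if (is.null(tr$sd) || is.null(tr$h2))
      stop("trait ", name, " needs either sd+h2 or V_g+V_e")
    resid <- tr$sd^2 - var_allom
    if (resid < 0)
      stop("allometric variance exceeds the target variance for trait ", name)
    Vg <- tr$h2 * resid
    Ve <- (1 - tr$h2) * resid
  }
  if (Vg < 0 || Ve < 0) stop("variance components must be >= 0")
  list(mean = tr$mean, b = b, c = c_scale, V_g = Vg, V_e = Ve,
       var_allom = var_allom)
}

#' Model-implied correlation between tree height and a trait
#'
#' Closed-form ramet-level Pearson correlation between height `h` and a
#' generated trait `c * h^b + genetic + noise`, from the log-normal mixture
#' moments of the height model. Used both to calibrate the default
#' allometric exponents and as the oracle for Monte-Carlo checks of the
#' generator; planted dosage effects are not included.
#'
#' @param config A [sim_config()].
#' @param trait Trait name (e.g. `"MVD"`).
#' @return Expected Pearson correlation.
#' @export
expected_th_correlation <- function(config, trait) {
  par <- resolve_trait(config, trait)
  m1 <- height_moment(config, 1)
  var_h <- height_moment(config, 2) - m1^2
  cov_ <- par$c * (height_moment(config, par$b + 1) -
                     m1 * height_moment(config, par$b))
  var_x <- par$var_allom + par$V_g + par$V_e
  cov_ / sqrt(var_h * var_x)
}

# solve b so the model-implied height correlation hits the trait's cor_th
# target (at fixed total trait variance sd^2)
solve_allometric_exponent <- function(config, name) {
  tr <- config$traits[[name]]
  target <- tr$cor_th
  if (is.null(tr$sd)) stop("cor_th calibration requires a trait sd")
  m1 <- height_moment(config, 1)
  var_h <- height_moment(config, 2) - m1^2
  f <- function(b) {
    c_scale <- tr$mean / height_moment(config, b)
    cov_ <- c_scale * (height_moment(config, b + 1) -
                         m1 * height_moment(config, b))
    cov_ / sqrt(var_h) / tr$sd - target
  }
  interval <- if (target > 0) c(1e-6, 4) else c(-4, -1e-6)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi))
    stop("target height correlation unattainable for trait ", name)
  stats::uniroot(f, interval, tol = 1e-8)$root
}

#' Simulate the indel complement of an irradiation-hybrid population
#'
#' Draws the lesion lines and their insertion/deletion intervals. Exactly
#' `round(n_lines * frac_lesion_lines)` lines carry at least one indel; the
#' remaining lines are dosage-normal controls. Indel starts are uniform on
#' the chromosome (chromosomes weighted by length), lengths log-normal
#' truncated to the chromosome, and indels of the same line never overlap
#' (a single irradiated gamete cannot lose or gain the same region twice);
#' indels of different lines overlap freely, which is what creates shared
#' genomic bins.
#'
#' @param genome A [genome] object.
#' @param config A [sim_config()]. `config$seed` fixes all randomness;
#'   identical inputs give identical output.
#' @return A list with `indels` (data frame: `chrom`, `start`, `end`,
#'   `line_id`, `kind`, `ploidy`) and `truth` (a `"ground_truth"` list:
#'   line ids, lesion lines, per-trait heritabilities and allometric
#'   coefficients, planted effects with realized per-line RDS).
#' @export
simulate_indel_population <- function(genome, config) {
  genome <- as_genome(genome)
  stopifnot(inherits(config, "sim_config"))
  ind <- config$indels
  set.seed(config$seed)
  lines <- sprintf("L%03d", seq_len(config$n_lines))
  n_lesion <- round(config$n_lines * config$frac_lesion_lines)
  if (n_lesion > 0 && ind$min_len >= max(genome))
    stop("minimum indel length exceeds every chromosome; rejecting config")
  lesion <- sort(sample(lines, n_lesion))
  rows <- list()
  for (ln in lesion) {
    cnt <- 1L + stats::rpois(1, max(0, ind$mean_count - 1))
    placed <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
    for (i in seq_len(cnt)) {
      for (attempt in 1:1000) {
        chr <- sample(names(genome), 1, prob = as.numeric(genome))
        clen <- unclass(genome)[[chr]]
        len <- ind$min_len + stats::rlnorm(1, ind$len_meanlog, ind$len_sdlog)
        if (len >= clen) next
        start <- floor(stats::runif(1, 0, clen - len))
        end <- floor(start + len)
        same <- placed[placed$chrom == chr, , drop = FALSE]
        if (nrow(same) && any(same$start < end & same$end > start)) next
        placed <- rbind(placed, data.frame(chrom = chr, start = start, end = end))
        break
      }
      if (nrow(placed) < i)
        stop("could not place a non-overlapping indel; rejecting config")
    }
    placed$line_id <- ln
    placed$kind <- ifelse(stats::runif(nrow(placed)) < ind$ins_frac, "INS", "DEL")
    placed$ploidy <- config$ploidy
    rows[[ln]] <- placed
  }
  indels <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               line_id = character(0), kind = character(0), ploidy = numeric(0))
  row.names(indels) <- NULL
  truth <- ground_truth(genome, config, lines, lesion, indels)
  list(indels = indels, truth = truth)
}

ground_truth <- function(genome, config, lines, lesion, indels) {
  h2 <- vapply(names(config$traits), function(nm) {
    par <- resolve_trait(config, nm)
    if (par$V_g + par$V_e == 0) 1 else par$V_g / (par$V_g + par$V_e)
  }, numeric(1))
  allom <- do.call(rbind, lapply(names(config$traits), function(nm) {
    par <- resolve_trait(config, nm)
    data.frame(trait = nm, a = log10(par$c), b = par$b,
               V_g = par$V_g, V_e = par$V_e)
  }))
  planted <- config$planted_effects
  planted_rds <- NULL
  if (!is.null(planted) && nrow(planted)) {
    planted_rds <- vapply(seq_len(nrow(planted)), function(i)
      rds_at(indels, lines, planted$chrom[i], planted$pos[i], config$ploidy),
      numeric(length(lines)))
    if (is.null(dim(planted_rds)))
      planted_rds <- matrix(planted_rds, nrow = length(lines))
    dimnames(planted_rds) <- list(lines, NULL)
  }
  structure(list(genome = genome, config = config, lines = lines,
                 lesion_lines = lesion, h2 = h2, allometry = allom,
                 planted = planted, planted_rds = planted_rds),
            class = "ground_truth")
}

#' Relative dosage score of every line at one genomic position
#'
#' @param indels Indel data frame.
#' @param lines Character vector of line ids (controls included).
#' @param chrom,pos Genomic position (bp).
#' @param ploidy Background ploidy for lines without indel records.
#' @return Named numeric vector of RDS values.
#' @export
rds_at <- function(indels, lines, chrom, pos, ploidy = 2) {
  out <- stats::setNames(rep(1, length(lines)), lines)
  hit <- indels[indels$chrom == chrom & indels$start <= pos & indels$end > pos, ,
                drop = FALSE]
  if (nrow(hit)) {
    delta <- tapply(ifelse(hit$kind == "INS", 1, -1) / hit$ploidy,
                    hit$line_id, sum)
    keep <- intersect(names(delta), lines)
    out[keep] <- out[keep] + delta[keep]
  }
  out
}

#' Simulate clonally replicated trait data with planted dosage effects
#'
#' Generates per-ramet phenotypes for every line. Tree height is drawn from
#' a hierarchical log-normal model (line effect + ramet noise, lesion lines
#' shifted down by the configured penalty, truncated at the configured
#' minimum). Height-dependent traits follow a power-law allometry
#' `c * height^b` plus a line-level genetic value (variance `V_g`), planted
#' dosage effects `effect * (RDS - 1)` summed over planted loci, and
#' independent ramet noise (variance `V_e`). Deletions and insertions
#' therefore shift a trait in opposite directions unless an effect is
#' declared one-sided. Trait values are floored at a small positive value.
#'
#' Randomness is fixed by `config$seed` (offset from the indel draw so both
#' stages are reproducible independently).
#'
#' @param indels Indel data frame from [simulate_indel_population()].
#' @param truth The matching `"ground_truth"` object.
#' @param config The same [sim_config()].
#' @return Data frame with one row per ramet: `line_id`, `ramet_id`, `TH`
#'   and one column per configured trait. The per-line genetic values and
#'   line heights used are attached as attributes `line_genetic` (matrix)
#'   and `line_height` (vector) for recovery testing.
#' @export
simulate_traits <- function(indels, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  lines <- truth$lines
  n <- length(lines)
  r <- config$n_replicates
  set.seed(config$seed + 1L)
  p <- height_params(config)
  is_lesion <- lines %in% truth$lesion_lines
  mu_line <- p$mu0 + p$delta * is_lesion + stats::rnorm(n, 0, sqrt(p$s2_g))
  planted <- truth$planted
  planted_shift <- function(trait_name) {
    shift <- rep(0, n)
    if (is.null(planted) || nrow(planted) == 0) return(shift)
    for (i in which(planted$trait == trait_name)) {
      rds <- truth$planted_rds[lines, i]
      dev <- rds - 1
      if (planted$side[i] == "del_only") dev[dev > 0] <- 0
      if (planted$side[i] == "ins_only") dev[dev < 0] <- 0
      shift <- shift + planted$effect[i] * dev
    }
    shift
  }
  line_idx <- rep(seq_len(n), each = r)
  h_ram <- exp(mu_line[line_idx] + stats::rnorm(n * r, 0, sqrt(p$s2_e)))
  h_ram <- pmax(config$height$min, h_ram + planted_shift("TH")[line_idx])
  out <- data.frame(line_id = lines[line_idx],
                    ramet_id = rep(seq_len(r), times = n),
                    TH = h_ram)
  gen <- matrix(0, n, length(config$traits),
                dimnames = list(lines, names(config$traits)))
  for (nm in names(config$traits)) {
    par <- resolve_trait(config, nm)
    g <- stats::rnorm(n, 0, sqrt(par$V_g))
    gen[, nm] <- g
    e <- stats::rnorm(n * r, 0, sqrt(par$V_e))
    y <- par$c * h_ram^par$b + (g + planted_shift(nm))[line_idx] + e
    out[[nm]] <- pmax(y, par$mean * 1e-6)
  }
  attr(out, "line_genetic") <- gen
  attr(out, "line_height") <- exp(mu_line + p$s2_e / 2)
  out
}

#' Simulate a complete synthetic population
#'
#' Convenience wrapper running [simulate_indel_population()] and
#' [simulate_traits()] with a shared configuration.
#'
#' @param genome A [genome]; defaults to [populus_genome()].
#' @param config A [sim_config()].
#' @return A list with `indels`, `traits` and `truth`.
#' @export
simulate_population <- function(genome = populus_genome(),
                                config = sim_config()) {
  sim <- simulate_indel_population(genome, config)
  traits <- simulate_traits(sim$indels, sim$truth, config)
  list(indels = sim$indels, traits = traits, truth = sim$truth)
}

#' Simulate a segmented stem cross-section
#'
#' Places vessels as discs in a square xylem region and jitters each disc
#' into a polygon so that measured perimeters carry realistic segmentation
#' noise (circularity < 1). With `clustering = 0` every vessel is solitary
#' (all pairwise centre distances exceed the sum of radii plus a safety
#' gap); with `clustering > 0` vessels are laid out in touching chains whose
#' lengths are geometric with continuation probability `clustering`, capped
#' at `max_group_size`.
#'
#' @param n_vessels Number of vessels (>= 1).
#' @param diameter_mean,diameter_sd Normal diameter distribution, um
#'   (truncated at 4 um).
#' @param clustering Chain continuation probability in `[0, 1]`.
#' @param xylem_area_mm2 Section area in mm^2.
#' @param jitter Relative radial noise of the polygon outline (0 = smooth).
#' @param max_group_size Largest allowed contact chain.
#' @param section_id Label for the emitted section.
#' @param seed Integer seed.
#' @return A list with `vessels` (data frame: `section_id`, `vessel_id`,
#'   `x_um`, `y_um`, `area_um2`, `perimeter_um`) and `section` (one-row data
#'   frame: `section_id`, `xylem_area_mm2`, `bark_thickness_um`).
#' @export
simulate_cross_section <- function(n_vessels, diameter_mean = 26,
                                   diameter_sd = 4, clustering = 0,
                                   xylem_area_mm2 = 1, jitter = 0.03,
                                   max_group_size = Inf,
                                   section_id = "S1", seed = 1L) {
  stopifnot(n_vessels >= 1, xylem_area_mm2 > 0,
            clustering >= 0, clustering <= 1, jitter >= 0)
  set.seed(seed)
  side <- sqrt(xylem_area_mm2) * 1000  # um
  radius <- pmax(2, stats::rnorm(n_vessels, diameter_mean, diameter_sd)) / 2
  if (sum(pi * radius^2) > 0.55 * side^2)
    stop("requested vessels cannot be packed into the xylem area")
  gap <- 4  # um separation beyond touching, so solitary stays solitary
  # chain memberships
  chain <- integer(n_vessels)
  cur <- 0L; size <- 0L
  for (i in seq_len(n_vessels)) {
    if (cur == 0L || size >= max_group_size || stats::runif(1) >= clustering) {
      cur <- cur + 1L; size <- 0L
    }
    chain[i] <- cur; size <- size + 1L
  }
  x <- y <- numeric(n_vessels)
  ok_place <- function(i, xi, yi) {
    if (xi < radius[i] || yi < radius[i] ||
        xi > side - radius[i] || yi > side - radius[i]) return(FALSE)
    prev <- seq_len(i - 1L)
    if (!length(prev)) return(TRUE)
    d2 <- (x[prev] - xi)^2 + (y[prev] - yi)^2
    lim <- (radius[prev] + radius[i] + gap)^2
    same <- chain[prev] == chain[i]
    touch_target <- if (any(same)) max(which(same)) else 0L
    if (touch_target > 0L) {
      # must clear everything except its chain predecessor (placed touching)
      clear <- all(d2[prev != touch_target] > lim[prev != touch_target])
      return(clear)
    }
    all(d2 > lim)
  }
  for (i in seq_len(n_vessels)) {
    same <- which(chain[seq_len(i - 1L)] == chain[i])
    placed <- FALSE
    for (attempt in 1:2000) {
      if (length(same)) {
        j <- max(same)
        ang <- stats::runif(1, 0, 2 * pi)
        xi <- x[j] + (radius[i] + radius[j]) * cos(ang)
        yi <- y[j] + (radius[i] + radius[j]) * sin(ang)
      } else {
        xi <- stats::runif(1, radius[i], side - radius[i])
        yi <- stats::runif(1, radius[i], side - radius[i])
      }
      if (ok_place(i, xi, yi)) { x[i] <- xi; y[i] <- yi; placed <- TRUE; break }
    }
    if (!placed) stop("could not place vessel ", i, "; packing infeasible")
  }
  # jitter each disc into a polygon; area/perimeter measured on the polygon
  K <- 48L
  th <- 2 * pi * (seq_len(K) - 1) / K
  area <- per <- numeric(n_vessels)
  for (i in seq_len(n_vessels)) {
    rr <- radius[i] * pmax(0.2, 1 + stats::rnorm(K, 0, jitter))
    px <- rr * cos(th); py <- rr * sin(th)
    nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
    area[i] <- abs(sum(px * ny - nx * py)) / 2
    per[i] <- sum(sqrt((nx - px)^2 + (ny - py)^2))
  }
  vessels <- data.frame(section_id = section_id,
                        vessel_id = seq_len(n_vessels),
                        x_um = x, y_um = y,
                        area_um2 = area, perimeter_um = per)
  section <- data.frame(section_id = section_id,
                        xylem_area_mm2 = xylem_area_mm2,
                        bark_thickness_um = NA_real_)
  list(vessels = vessels, section = section)
}
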