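# 3D U-Net model specification and construction.
#
# Architecture: four down/upsampling levels.  Each level applies two conv
# blocks (3x3x3 conv, stride 1, pad 1 -> instance norm -> ReLU); downsampling
# is 2x max pooling, upsampling a 2x2x2 stride-2 transposed convolution
# followed by skip concatenation; a final 1x1x1 convolution maps to one
# output channel per structure.  Output channels are independent per-channel
# sigmoids (multi-label): structures may overlap and labels can be missing
# per structure, which a softmax would forbid.  Convolutions carry no bias
# (absorbed by the instance-norm shift).

#' Specify a segmentation model
#'
#' Input channel count follows the regime: the reference (RM) and
#' patient-specific (PSM) models take only the mid-treatment image (C = 1);
#' the general adaptive model (GAM) takes the mid-treatment image plus the
#' aligned pre-treatment image and its S label channels (C = 2 + S), e.g.
#' 19 channels for 17 structures.
#'
#' @param structures character vector of structure names (fixed cohort
#'   order) or an integer count.
#' @param regime `"RM"`, `"PSM"` or `"GAM"`.
#' @param width base channel width of the first level; doubles per level.
#' @return An object of class `model_spec` with fields `in_channels`,
#'   `out_channels`, `depth`, `width`, `structures`.
#' @export
model_spec <- function(structures, regime = c("RM", "PSM", "GAM"), width = 8L) {
  regime <- match.arg(regime)
  if (is.numeric(structures)) structures <- sprintf("s%02d", seq_len(structures))
  S <- length(structures)
  C <- if (regime == "GAM") 2L + S else 1L
  structure(list(in_channels = C, out_channels = S, depth = 4L,
                 width = as.integer(width), regime = regime,
                 structures = structures, norm = "instance",
                 activation = "relu"),
            class = "model_spec")
}

# parameter layout in the exact order the C++ engine consumes it
unet_layout <- function(C, S, width) {
  rows <- list()
  add <- function(name, type, Cin, Cout, n)
    rows[[length(rows) + 1]] <<- data.frame(name = name, type = type,
                                            Cin = Cin, Cout = Cout, n = n)
  cprev <- C
  for (d in 0:4) {
    wd <- if (d < 4) width * 2^d else width * 16
    for (j in 1:2) {
      cin <- if (j == 1) cprev else wd
      add(sprintf("enc%d_conv%d", d, j), "conv", cin, wd, 27 * cin * wd)
      add(sprintf("enc%d_gamma%d", d, j), "gamma", wd, wd, wd)
      add(sprintf("enc%d_beta%d", d, j), "beta", wd, wd, wd)
    }
    cprev <- wd
  }
  for (d in 3:0) {
    wd <- width * 2^d
    wup <- if (d == 3) width * 16 else width * 2^(d + 1)
    add(sprintf("up%d_tconv", d), "tconv", wup, wd, 8 * wup * wd)
    for (j in 1:2) {
      cin <- if (j == 1) 2 * wd else wd
      add(sprintf("dec%d_conv%d", d, j), "conv", cin, wd, 27 * cin * wd)
      add(sprintf("dec%d_gamma%d", d, j), "gamma", wd, wd, wd)
      add(sprintf("dec%d_beta%d", d, j), "beta", wd, wd, wd)
    }
  }
  add("final_W", "final", width, S, S * width)
  add("final_b", "bias", S, S, S)
  out <- do.call(rbind, rows)
  out$offset <- cumsum(c(0, head(out$n, -1)))
  out
}

#' Build (initialize) a U-Net model
#'
#' He-normal initialization for convolution weights, unit gain / zero shift
#' for instance norm, and a negative final bias so the initial foreground
#' probability is small (foreground is rare in multi-organ segmentation).
#'
#' @param spec a [model_spec()].
#' @param grid_dim length-3 grid the model will run on; every dimension
#'   must be divisible by 2^4 = 16 (four pooling levels).
#' @param seed integer seed for the weight draw.
#' @return An object of class `adaptseg_net`.
#' @export
build_model <- function(spec, grid_dim, seed = 1L) {
  grid_dim <- as.integer(grid_dim)
  if (any(grid_dim %% 16L != 0L))
    stop(sprintf(paste("grid dimensions (%s) must be divisible by 16;",
                       "pad to (%s)"),
                 paste(grid_dim, collapse = "x"),
                 paste(16L * ceiling(grid_dim / 16), collapse = "x")))
  lay <- unet_layout(spec$in_channels, spec$out_channels, spec$width)
  par <- numeric(sum(lay$n))
  local_rng(seed, {
    for (i in seq_len(nrow(lay))) {
      idx <- lay$offset[i] + seq_len(lay$n[i])
      par[idx] <- switch(lay$type[i],
        conv = rnorm(lay$n[i], sd = sqrt(2 / (27 * lay$Cin[i]))),
        tconv = rnorm(lay$n[i], sd = sqrt(2 / (8 * lay$Cin[i]))),
        gamma = 1,
        beta = 0,
        final = rnorm(lay$n[i], sd = sqrt(1 / lay$Cin[i])),
        bias = -2)
    }
  })
  structure(list(spec = spec, par = par, layout = lay, grid_dim = grid_dim,
                 n_params = length(par)),
            class = "adaptseg_net")
}

#' @export
print.adaptseg_net <- function(x, ...) {
  cat(sprintf("<adaptseg_net> 3D U-Net, %s regime: C=%d -> S=%d, width %d, depth %d, %s parameters\n",
              x$spec$regime, x$spec$in_channels, x$spec$out_channels,
              x$spec$width, x$spec$depth, format(x$n_params, big.mark = ",")))
  invisible(x)
}

# stack input channels (x,y,z,C) into the C x V matrix the engine expects
flatten_channels <- function(arr) {
  d <- dim(arr)
  if (length(d) == 3) d <- c(d, 1L)
  matrix(aperm(array(arr, d), c(4, 1, 2, 3)), nrow = d[4])
}

unflatten_channels <- function(m, grid_dim) {
  aperm(array(m, c(nrow(m), grid_dim)), c(2, 3, 4, 1))
}

#' Forward pass: per-structure probability maps
#'
#' @param net an [build_model()] network (possibly trained).
#' @param input array `(x, y, z, C)` (or `(x, y, z)` for C = 1) matching the
#'   spec's channel count and order: mid image, then for GAM the aligned
#'   pre image and the S pre label channels in cohort structure order.
#' @return Array `(x, y, z, S)` of independent probabilities in `[0, 1]`;
#'   binarize at 0.5 for evaluation.
#' @export
unet_predict <- function(net, input) {
  x <- flatten_channels(input)
  gd <- dim(input)[1:3]
  if (nrow(x) != net$spec$in_channels)
    stop(sprintf("input has %d channels, spec requires %d", nrow(x),
                 net$spec$in_channels))
  if (any(gd %% 16L != 0L))
    stop(sprintf("grid (%s) not divisible by 16", paste(gd, collapse = "x")))
  out <- unet_run_cpp(net$par, net$spec$out_channels, net$spec$width,
                      as.integer(gd), x, want_probs = TRUE)
  unflatten_channels(out$probs, gd)
}

#' Serialize model weights with a JSON spec sidecar
#'
#' The sidecar records channel counts, width and the structure order so
#' that inference can validate channel compatibility.
#'
#' @param net an `adaptseg_net`.
#' @param path base path; writes `<path>.bin.txt` (weights, one value per
#'   line) and `<path>.json`.
#' @export
write_model <- function(net, path) {
  writeLines(format(net$par, digits = 17), paste0(path, ".bin.txt"))
  jsonlite::write_json(list(in_channels = net$spec$in_channels,
                            out_channels = net$spec$out_channels,
                            width = net$spec$width, depth = net$spec$depth,
                            regime = net$spec$regime,
                            structures = net$spec$structures,
                            grid_dim = net$grid_dim),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(paste0(path, ".json"))
  spec <- model_spec(unlist(j$structures), j$regime, j$width)
  stopifnot(spec$in_channels == j$in_channels)
  net <- build_model(spec, unlist(j$grid_dim))
  par <- as.numeric(readLines(paste0(path, ".bin.txt")))
  if (length(par) != net$n_params) stop("weight file does not match spec")
  net$par <- par
  net
}
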