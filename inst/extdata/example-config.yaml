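# Example configuration for the histoscale CLI.
# Any field can also be given as a --flag, which takes precedence.

# ---- simulate: synthetic paired cohort ------------------------------------
n_patients: 40        # bulk slides (one per patient)
patches_per_slide: 30
n_spot_slides: 10     # spatial slides (distinct patients)
spots_per_slide: 50
n_genes: 20           # target panel size G
embed_dim: 16         # patch-embedding dimensionality d
latent_dim: 4         # latent morphology factors driving the synthesis
noise_sd: 0           # Gaussian noise on embeddings; 0 = exact affine map
count_depth: .inf     # finite value => Poisson counts with that library size
seed: 0               # master seed; every stage draws from named substreams

# ---- prep-expr -------------------------------------------------------------
min_genes: 100        # spots need >= this many detected genes

# ---- prep-wsi --------------------------------------------------------------
patch_size: 256       # tile side, pixels (20x magnification, 0.5 um/px input)
min_coverage: 0.15    # tiles below this tissue fraction are discarded
min_tiles: 1000       # slides need strictly more retained tiles than this
dim: 512              # encoder output dimensionality

# ---- pretrain / finetune ---------------------------------------------------
max_epochs: 200
lr: null              # null = stage default (2e-4 pretrain, 2e-5 finetune)
weight_decay: 5.0e-3
patience: 20          # early-stopping window, epochs
lambda: 0.1           # loss-mixing weight; up-sampling factor = round(1/lambda)
val_frac: 0.10        # fraction of training patients held out for validation
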