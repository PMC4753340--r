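# Example dcfseg pipeline configuration (the published operating point).
# Pass with `dcfseg extract <image> --config dcfseg-config.yaml ...`;
# command-line flags override file values.
roi: [144, 150, 656, 450]   # x0, y0, x1, y1 (0-based, half-open)
alpha_cut: 0.5              # fuzzy membership cut
noise_size_frac: 0.085      # object removed if smaller than this ROI-area fraction
left_margin_frac: 0.1       # ...or starting within this width fraction of the margin
min_width_frac: 0.5         #    while narrower than this width fraction
connectivity: 8             # blob labeling connectivity (4 or 8)
bridge_iterations: 1        # neighbor-gap bridging passes
expand_radius: 2            # vertebra-candidate dilation radius (px)
restore_divisor: 1000       # distance-weight divisor of the restoration step
side: left                  # which side the leading vertebra occupies
pixel_spacing: [0.01, 0.01] # cm/px calibration; overrides any embedded DICOM
                            # PixelSpacing. Remove this line to use the image's
                            # own calibration (pixel-unit output if none).
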