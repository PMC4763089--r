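# Units

All quantities are SI-derived mm / s / rad unless a column name says
otherwise:

| quantity                    | unit    | notes                                   |
|-----------------------------|---------|-----------------------------------------|
| positions x, y, rho, delta  | mm      | arena frame; pixel (r, c) center at ((c-0.5)px, (r-0.5)px) |
| angles theta, alpha, heading| rad     | alpha in (-pi, pi], 0 = outward radial (counterflow) |
| curvature kappa             | 1/mm    | signed; + = center of curvature right of the heading |
| time t, tau, tau_b, lambda  | s       |                                          |
| speeds u, v_f, flow_speed   | mm/s    | v_f reported positive toward the sink    |
| volumetric rate Q_v         | mm^3/s  | 1 mL/s = 1000 mm^3/s                    |
| surfacic rate q             | mm^2/s  | Q_v / (2 pi h)                          |
| depth h, body length L      | mm      |                                          |
| frame_rate                  | Hz      |                                          |
| pixel_size                  | mm/px   | 35 um = 0.035                           |
| image intensity             | [0, 1]  | written to disk as 16-bit grayscale     |
| areas                       | px      | blob pixel counts                       |
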