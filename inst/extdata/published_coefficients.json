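{"model":"biquadratic tz surfaces","amplitude_unit":"mV","valid_d_range":[25,90],"valid_r_range":[50,500],"source":"published","residuals":{"mean_abs":[0.005,0.003],"rms":["NA","NA"]},"coefficients":[{"i":1,"j":1,"k":1,"value":0.951,"printed":"9.5100E-01"},{"i":2,"j":1,"k":1,"value":0.83844,"printed":"8.3844E-01"},{"i":1,"j":2,"k":1,"value":-0.0073845,"printed":"-7.3845E-03"},{"i":2,"j":2,"k":1,"value":-0.002492,"printed":"-2.4920E-03"},{"i":1,"j":3,"k":1,"value":2.5574e-05,"printed":"2.5574E-05"},{"i":2,"j":3,"k":1,"value":3.4911e-06,"printed":"3.4911E-06"},{"i":1,"j":1,"k":2,"value":-0.22321,"printed":"-2.2321E-01"},{"i":2,"j":1,"k":2,"value":-0.51557,"printed":"-5.1557E-01"},{"i":1,"j":2,"k":2,"value":0.00034212,"printed":"3.4212E-04"},{"i":2,"j":2,"k":2,"value":-0.00019468,"printed":"-1.9468E-04"},{"i":1,"j":3,"k":2,"value":-3.3074e-06,"printed":"-3.3074E-06"},{"i":2,"j":3,"k":2,"value":1.9169e-06,"printed":"1.9169E-06"},{"i":1,"j":1,"k":3,"value":0.20358,"printed":"2.0358E-01"},{"i":2,"j":1,"k":3,"value":0.088151,"printed":"8.8151E-02"},{"i":1,"j":2,"k":3,"value":-0.0016564,"printed":"-1.6564E-03"},{"i":2,"j":2,"k":3,"value":0.00032125,"printed":"3.2125E-04"},{"i":1,"j":3,"k":3,"value":6.4493e-06,"printed":"6.4493E-06"},{"i":2,"j":3,"k":3,"value":3.2255e-07,"printed":"3.2255E-07"}]}
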