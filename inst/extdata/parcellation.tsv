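voxel_id	x_mm	y_mm	z_mm	roi_label
1	11.499999999999996	43.5	-60.5	ROI01
2	11.499999999999996	35.500000000000007	-60.5	ROI01
3	11.499999999999996	51.500000000000007	-20.499999999999996	ROI02
4	3.5000000000000031	51.500000000000007	-20.499999999999996	ROI02
5	27.500000000000011	-4.4999999999999902	3.5000000000000031	ROI03
6	27.500000000000011	-4.4999999999999902	-4.4999999999999902	ROI03
7	-20.499999999999996	3.5000000000000031	3.5000000000000031	ROI04
8	-20.499999999999996	3.5000000000000031	-4.4999999999999902	ROI04
9	59.500000000000014	11.499999999999996	-4.4999999999999902	ROI05
10	59.500000000000014	3.5000000000000031	-4.4999999999999902	ROI05
11	11.499999999999996	51.500000000000007	27.500000000000011	ROI06
12	3.5000000000000031	51.500000000000007	27.500000000000011	ROI06
13	67.500000000000014	-12.499999999999996	3.5000000000000031	ROI07
14	67.500000000000014	-12.499999999999996	-4.4999999999999902	ROI07
15	-28.499999999999996	-36.5	-36.5	ROI08
16	-28.499999999999996	-36.5	-44.5	ROI08
17	27.500000000000011	-60.5	-20.499999999999996	ROI09
18	35.500000000000007	-60.5	-20.499999999999996	ROI09
19	43.5	-36.5	3.5000000000000031	ROI10
20	43.5	-36.5	-4.4999999999999902	ROI10
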