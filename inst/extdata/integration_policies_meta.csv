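"code","name","pub_date","disclosed"
"P1","Notice of the General Office of the State Council on Issuing the Outline of the National Health Care Service System Plan (2015-2020)","2015.03.06",TRUE
"P2","Notice of the General Office of the State Council Forwarding the Guidance Opinions of the National Health and Family Planning Commission and Other Departments on Promoting the Integration of Medical and Health Care Services with Older Adult Care Services","2015.11.18",TRUE
"P3","Notice of the State Council on Issuing the Outline of the Strategic Plan for the Development of Traditional Chinese Medicine (2016-2030)","2016.02.22",TRUE
"P4","Notice of the General Office of the National Health and Family Planning Commission on Issuing the Division of Responsibilities for Key Tasks in Integrating Medical Care and Older Adult Care","2016.04.01",TRUE
"P5","Notice of the General Office of the National Health and Family Planning Commission and the General Office of the Ministry of Civil Affairs on Issuing the Division of Responsibilities for Key Tasks in Integrating Medical Care and Older Adult Care","2016.04.07",TRUE
"P6","Notice of the Ministry of Civil Affairs and the National Development and Reform Commission on Issuing the 13th Five-Year Plan for the Development of Civil Affairs","2016.06.24",TRUE
"P7","The Central Committee of the Communist Party of China and the State Council issued the Healthy China 2030 Planning Outline","2016.10.25",TRUE
"P8","Opinions of the General Office of the State Council on Comprehensively Opening Up the Older Adult Care Service Market and Improving the Quality of Older Adult Care Services","2016.12.07",TRUE
"P9","Notice of the State Council on Issuing the 13th Five-Year Plan for the Development of the Older Adult Care Service and the Construction of the Older Adult Care System","2017.02.28",TRUE
"P10","Opinions of the General Office of the State Council on Promoting the Development of Older Adult Care Services","2019.03.29",TRUE
"P11","Notice on Doing a Good Job in the Approval and Registration of Medical and Nursing Care Institutions","2019.05.27",TRUE
"P12","Several Opinions on Deepening the Development of Medical Care and Older Adult Care Integration","2019.10.23",TRUE
"P13","Notice of the General Office of the National Health Commission, the General Office of the Ministry of Civil Affairs, and the Office of the National Administration of Traditional Chinese Medicine on Issuing the Service Guidelines for Medical and Older Adult Care Integration Institutions (Trial)","2019.12.23",TRUE
"P14","Notice from the Office of the National Health Commission, the Office of the Ministry of Civil Affairs, and the Office of the National Administration of Traditional Chinese Medicine on the Issuance of the Management Guidelines for Medical and Older Adult Care Integration Institutions (Trial Version)","2020.02.17",TRUE
"P15","Notice from the Office of the National Health Commission on the Selection of the First Batch of Pilot Institutions for Remote Collaborative Services Combining Medical Care and Older Adult Health Care","2020.08.28",TRUE
"P16","Notice from the Office of the National Health Commission, the Office of the Ministry of Civil Affairs, and the Office of the National Administration of Traditional Chinese Medicine on the Issuance of the Management Guidelines for Medical and Older Adult Care Integration Institutions (Trial Version)","2020.09.27",TRUE
"P17","Opinion of the Ministry of Housing and Urban-Rural Development, the National Development and Reform Commission, the Ministry of Civil Affairs, the National Health Commission, the Medical Insurance Bureau, and the National Committee on Aging on Promoting the Development of Home-Based and Community-Based Older Adult Care Services by Property Service Enterprises","2020.11.24",TRUE
"P18","Notice on Launching a Quality Improvement Campaign for Medical and Nursing Care Institutions","2020.12.03",TRUE
"P19","Opinions of the General Office of the State Council on Promoting the Healthy Development of Older Adult Care and Childcare Services","2020.12.14",TRUE
"P20","Notice from the Ministry of Industry and Information Technology, the Ministry of Civil Affairs, and the National Health Commission on the Issuance of the Action Plan for the Development of the Smart Health and Aging Industry (2021-2025)","2021.10.20",TRUE
"P21","Opinions of the Central Committee of the Communist Party of China and the State Council on Strengthening Aging Work in the New Era","2021.11.18",TRUE
"P22","Notice of the State Council on Issuing the 14th Five-Year Plan for the Development of the National Aging Cause and the Older Adult Care Service System","2021.12.30",TRUE
"P23","Notice on Launching an Initiative to Enhance Community Medical and Older Adult Care Integration Capabilities","2022.03.23",TRUE
"P24","Guiding Opinions on Further Promoting the Development of Medical Care and Older Adult Care Integration Issued by the National Health Commission and Ten Other Departments","2022.07.18",TRUE
"P25","Notice on Promoting Typical Experiences from Pilot Programs Combining Medical Care and Older Adult Care","2023.03.14",TRUE
"P26","Notice on the Issuance of the Guidelines for Home-based and Community-based Medical and Nursing Care Services (Trial Version)","2023.11.01",TRUE
"P27","Guiding Opinions on Promoting High-Quality Development of Medical and Older Adult Care Integration Services Issued by the National Health Commission and Four Other Departments","2024.12.12",TRUE
"P28","Opinions of the Central Committee of the Communist Party of China and the State Council on Deepening the Reform and Development of Older Adult Care Services","2024.12.30",TRUE
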